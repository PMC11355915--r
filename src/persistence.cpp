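#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Disjoint-set union with path halving. Each root carries the filtration
// value and tie-break index of the oldest cell in its component.
struct DSU {
  std::vector<int> parent;
  std::vector<double> birth;
  std::vector<int> birth_idx;
  DSU(int n) : parent(n), birth(n), birth_idx(n) {
    std::iota(parent.begin(), parent.end(), 0);
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
};

// Elder rule: the root with the smaller birth value survives; ties broken by
// the smaller birth index so the pairing is deterministic.
static inline bool elder(const DSU &d, int ra, int rb) {
  if (d.birth[ra] != d.birth[rb]) return d.birth[ra] < d.birth[rb];
  return d.birth_idx[ra] < d.birth_idx[rb];
}

// 0-dimensional persistence of the sublevel-set filtration on the vertex
// construction: pixels are vertices born at their value, 4-neighbour edges
// born at the max of their endpoints. The one essential component is killed
// at the global maximum so downstream lifetime sums are finite.
// [[Rcpp::export(name = ".cubical_pers0")]]
List cubical_pers0(NumericMatrix z) {
  const int N = z.nrow(), M = z.ncol(), n = N * M;
  std::vector<double> v(n);
  for (int j = 0; j < M; ++j)
    for (int i = 0; i < N; ++i) v[j * N + i] = z(i, j);

  // edges as (value, endpoint a, endpoint b)
  const int ne = (N - 1) * M + N * (M - 1);
  std::vector<double> ew(ne);
  std::vector<int> ea(ne), eb(ne);
  int k = 0;
  for (int j = 0; j < M; ++j)
    for (int i = 0; i + 1 < N; ++i) { // vertical
      int a = j * N + i, b = j * N + i + 1;
      ea[k] = a; eb[k] = b; ew[k] = std::max(v[a], v[b]); ++k;
    }
  for (int j = 0; j + 1 < M; ++j)
    for (int i = 0; i < N; ++i) { // horizontal
      int a = j * N + i, b = (j + 1) * N + i;
      ea[k] = a; eb[k] = b; ew[k] = std::max(v[a], v[b]); ++k;
    }

  std::vector<int> ord(ne);
  std::iota(ord.begin(), ord.end(), 0);
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return ew[a] < ew[b]; });

  DSU dsu(n);
  for (int i = 0; i < n; ++i) { dsu.birth[i] = v[i]; dsu.birth_idx[i] = i; }

  std::vector<double> births, deaths;
  births.reserve(n); deaths.reserve(n);
  for (int e = 0; e < ne; ++e) {
    int idx = ord[e];
    int ra = dsu.find(ea[idx]), rb = dsu.find(eb[idx]);
    if (ra == rb) continue;
    int survivor = elder(dsu, ra, rb) ? ra : rb;
    int victim = (survivor == ra) ? rb : ra;
    births.push_back(dsu.birth[victim]);
    deaths.push_back(ew[idx]);
    dsu.parent[victim] = survivor;
  }

  double vmin = *std::min_element(v.begin(), v.end());
  double vmax = *std::max_element(v.begin(), v.end());
  births.push_back(vmin);
  deaths.push_back(vmax);
  LogicalVector ess(births.size(), false);
  ess[births.size() - 1] = true;
  return List::create(_["birth"] = births, _["death"] = deaths,
                      _["essential"] = ess);
}

// 1-dimensional persistence via the dual graph. In a planar grid complex no
// set of squares has empty boundary, so every square kills a loop; a loop
// born at edge value b is filled at the value of the oldest face of the
// complement component it bounds. Running union-find over the faces (plus an
// outer node) in decreasing filtration order yields exactly those pairs:
// merging across a primal edge of value w kills the component whose oldest
// face has the smaller value, emitting the pair (w, that face value).
// [[Rcpp::export(name = ".cubical_pers1")]]
List cubical_pers1(NumericMatrix z) {
  const int N = z.nrow(), M = z.ncol();
  if (N < 2 || M < 2)
    return List::create(_["birth"] = NumericVector(0),
                        _["death"] = NumericVector(0),
                        _["essential"] = LogicalVector(0));

  const int FR = N - 1, FC = M - 1, F = FR * FC;
  // node 0 = outer face (birth +Inf); faces are 1..F
  std::vector<double> fb(F + 1);
  fb[0] = R_PosInf;
  for (int c = 0; c < FC; ++c)
    for (int r = 0; r < FR; ++r) {
      double m = std::max(std::max(z(r, c), z(r + 1, c)),
                          std::max(z(r, c + 1), z(r + 1, c + 1)));
      fb[1 + c * FR + r] = m;
    }

  // dual edges: one per primal edge, linking its incident faces
  const int ne = (N - 1) * M + N * (M - 1);
  std::vector<double> ew(ne);
  std::vector<int> ea(ne), eb(ne);
  int k = 0;
  // vertical primal edge (r,c)-(r+1,c): faces left (r, c-1) and right (r, c)
  for (int c = 0; c < M; ++c)
    for (int r = 0; r + 1 < N; ++r) {
      ew[k] = std::max(z(r, c), z(r + 1, c));
      ea[k] = (c == 0) ? 0 : 1 + (c - 1) * FR + r;
      eb[k] = (c == M - 1) ? 0 : 1 + c * FR + r;
      ++k;
    }
  // horizontal primal edge (r,c)-(r,c+1): faces above (r-1, c) and below (r, c)
  for (int c = 0; c + 1 < M; ++c)
    for (int r = 0; r < N; ++r) {
      ew[k] = std::max(z(r, c), z(r, c + 1));
      ea[k] = (r == 0) ? 0 : 1 + c * FR + (r - 1);
      eb[k] = (r == N - 1) ? 0 : 1 + c * FR + r;
      ++k;
    }

  std::vector<int> ord(ne);
  std::iota(ord.begin(), ord.end(), 0);
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return ew[a] > ew[b]; });

  DSU dsu(F + 1);
  for (int i = 0; i <= F; ++i) { dsu.birth[i] = fb[i]; dsu.birth_idx[i] = i; }

  std::vector<double> births, deaths;
  births.reserve(F); deaths.reserve(F);
  for (int e = 0; e < ne; ++e) {
    int idx = ord[e];
    int ra = dsu.find(ea[idx]), rb = dsu.find(eb[idx]);
    if (ra == rb) continue;
    // in the reversed sweep the elder is the component with the LARGER birth
    int survivor, victim;
    if (dsu.birth[ra] != dsu.birth[rb])
      survivor = (dsu.birth[ra] > dsu.birth[rb]) ? ra : rb;
    else
      survivor = (dsu.birth_idx[ra] < dsu.birth_idx[rb]) ? ra : rb;
    victim = (survivor == ra) ? rb : ra;
    births.push_back(ew[idx]);       // loop born when this edge appears
    deaths.push_back(dsu.birth[victim]); // filled at the oldest face value
    dsu.parent[victim] = survivor;
  }
  LogicalVector ess(births.size(), false);
  return List::create(_["birth"] = births, _["death"] = deaths,
                      _["essential"] = ess);
}
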