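#' Parameters of the synthetic vessel-tree image model
#'
#' The generator draws a stylised retinal vasculature: a bright fundus-like
#' background with additive Gaussian noise, a brighter optic-disc ellipse,
#' and a dark recursive bifurcation tree rooted at the disc whose branch
#' width, length and contrast decay with depth. It is a topological stand-in,
#' not a physiological model: it gives images non-trivial component and loop
#' structure under sublevel filtration, which is all the asymmetry statistic
#' sees.
#'
#' @param depth Bifurcation generations per trunk (`0` = disc only).
#' @param n_trunks Number of primary vessels leaving the disc.
#' @param length_frac First-generation branch length as a fraction of the
#'   shorter image side.
#' @param length_decay,width_decay,contrast_decay Per-generation geometric
#'   decay factors in (0, 1].
#' @param width_frac First-generation branch half-width fraction.
#' @param branch_angle Mean bifurcation half-angle, radians.
#' @param angle_jitter SD of per-branch angular noise, radians.
#' @param contrast Intensity drop of first-generation vessels below
#'   background (vessels are dark).
#' @param background Background intensity in \[0, 1\].
#' @param noise_sd SD of pixel-wise Gaussian noise.
#' @param disc_radius_frac Optic-disc radius fraction.
#' @param disc_intensity Optic-disc intensity.
#' @return A named list of class `vessel_params`.
#' @export
vessel_params <- function(depth = 5, n_trunks = 3,
                          length_frac = 0.26, length_decay = 0.78,
                          width_frac = 0.030, width_decay = 0.78,
                          branch_angle = 0.55, angle_jitter = 0.22,
                          contrast = 0.55, contrast_decay = 0.88,
                          background = 0.85, noise_sd = 0.02,
                          disc_radius_frac = 0.09, disc_intensity = 0.95) {
  p <- as.list(environment())
  if (p$depth < 0 || p$n_trunks < 0) abort("depth and n_trunks must be >= 0.")
  structure(p, class = "vessel_params")
}

# Nodes per trunk for a full binary tree of the given depth.
n_tree_nodes <- function(params) {
  params$n_trunks * (2^params$depth - 1L)
}

# Grow the branch segments from a fixed node-indexed draw matrix (4 standard
# normals per node: angle jitter, log-length factor, branch-angle factor,
# log-width factor). Breadth-first per trunk, so the mapping draw -> branch
# is stable and a perturbed draw matrix regrows a coherent, connected tree.
grow_tree <- function(size, params, draws) {
  N <- size[1]; M <- size[2]
  if (params$depth == 0L || params$n_trunks == 0L)
    return(tibble(x0 = double(), y0 = double(), x1 = double(), y1 = double(),
                  width = double(), intensity = double(), level = integer()))
  s <- min(N, M)
  cx <- 0.5 * N; cy <- 0.26 * M  # disc centre (rows, cols)
  base_angles <- seq(-1.0, 1.0, length.out = max(params$n_trunks, 2))[seq_len(params$n_trunks)]

  segs <- vector("list", nrow(draws))
  node <- 0L
  for (t in seq_len(params$n_trunks)) {
    # queue entries: (x, y, angle, level)
    queue <- list(list(x = cx, y = cy, angle = base_angles[t], level = 0L))
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      node <- node + 1L
      d <- draws[node, ]
      ang <- q$angle + params$angle_jitter * d[1]
      len <- params$length_frac * s * params$length_decay^q$level * exp(0.18 * d[2])
      wid <- max(0.6, params$width_frac * s * params$width_decay^q$level * exp(0.15 * d[4]))
      inten <- params$background - params$contrast * params$contrast_decay^q$level
      x1 <- q$x + len * cos(ang); y1 <- q$y + len * sin(ang)
      segs[[node]] <- c(q$x, q$y, x1, y1, wid, inten, q$level)
      if (q$level + 1L < params$depth) {
        spread <- params$branch_angle * exp(0.20 * d[3])
        queue <- c(queue,
                   list(list(x = x1, y = y1, angle = ang - spread, level = q$level + 1L),
                        list(x = x1, y = y1, angle = ang + spread, level = q$level + 1L)))
      }
    }
  }
  m <- do.call(rbind, segs)
  tibble(x0 = m[, 1], y0 = m[, 2], x1 = m[, 3], y1 = m[, 4],
         width = m[, 5], intensity = m[, 6], level = as.integer(m[, 7]))
}

# Rasterise disc + segments onto background + noise. Vessels are stamped as
# discs along each segment, darkening (pmin) whatever is beneath.
render_vessels <- function(size, params, segments, noise) {
  N <- size[1]; M <- size[2]
  img <- matrix(params$background, N, M) + noise

  s <- min(N, M)
  cx <- 0.5 * N; cy <- 0.26 * M
  r <- params$disc_radius_frac * s
  ii <- matrix(seq_len(N), N, M)
  jj <- matrix(seq_len(M), N, M, byrow = TRUE)
  disc <- (ii - cx)^2 + (jj - cy)^2 <= r^2
  img[disc] <- params$disc_intensity + noise[disc]

  for (k in seq_len(nrow(segments))) {
    sg <- segments[k, ]
    len <- sqrt((sg$x1 - sg$x0)^2 + (sg$y1 - sg$y0)^2)
    nstep <- max(2L, ceiling(len / 0.6))
    ts <- seq(0, 1, length.out = nstep)
    xs <- sg$x0 + ts * (sg$x1 - sg$x0)
    ys <- sg$y0 + ts * (sg$y1 - sg$y0)
    hw <- sg$width / 2
    for (p in seq_len(nstep)) {
      i0 <- max(1L, floor(xs[p] - hw)); i1 <- min(N, ceiling(xs[p] + hw))
      j0 <- max(1L, floor(ys[p] - hw)); j1 <- min(M, ceiling(ys[p] + hw))
      if (i0 > i1 || j0 > j1) next
      iw <- i0:i1; jw <- j0:j1
      d2 <- outer((iw - xs[p])^2, (jw - ys[p])^2, `+`)
      sub <- img[iw, jw, drop = FALSE]
      hit <- d2 <= hw^2
      sub[hit] <- pmin(sub[hit], sg$intensity)
      img[iw, jw] <- sub
    }
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic vessel-tree fundus image
#'
#' Deterministic given `(size, params, seed)`; the global random-number state
#' is left untouched.
#'
#' @param size Integer vector `c(N, M)`, at least 32 in each dimension for
#'   non-trivial topology.
#' @param params A [vessel_params()] list.
#' @param seed Integer seed.
#' @return A [greyscale_image()] with values in \[0, 1\].
#' @examples
#' img <- make_vessel_image(c(64, 64), seed = 1)
#' @export
make_vessel_image <- function(size = c(128, 128), params = vessel_params(),
                              seed = 1) {
  check_size(size)
  if (params$depth == 0L || params$n_trunks == 0L)
    warn("degenerate vessel parameters: background and disc only.")
  nn <- max(n_tree_nodes(params), 1L)
  withr::with_seed(seed, {
    draws <- matrix(rnorm(nn * 4), nn, 4)
    noise <- matrix(rnorm(prod(size), sd = params$noise_sd), size[1], size[2])
  })
  segs <- grow_tree(size, params, draws)
  greyscale_image(render_vessels(size, params, segs, noise))
}

check_size <- function(size) {
  if (length(size) != 2L || any(size < 32))
    abort("`size` must be c(N, M) with both dimensions >= 32.")
}

#' Generate a left/right image pair with controlled asymmetry
#'
#' The left image is grown from a node-indexed matrix of random draws; the
#' right image regrows the same tree from those draws perturbed by
#' independent zero-mean noise of scale `a` (branch angles, lengths, widths
#' and contrasts all shift coherently down the tree). Pixel noise is shared,
#' so `a = 0` yields bit-identical fields and, downstream, an asymmetry
#' statistic of exactly 0; larger `a` produces increasingly different
#' vasculature.
#'
#' @inheritParams make_vessel_image
#' @param a Asymmetry level, `>= 0`.
#' @return A list with elements `left` and `right` ([greyscale_image()]s).
#' @examples
#' pr <- make_pair(c(64, 64), a = 0.3, seed = 2)
#' @export
make_pair <- function(size = c(128, 128), params = vessel_params(), a = 0,
                      seed = 1) {
  check_size(size)
  if (a < 0) abort("`a` must be >= 0.")
  nn <- max(n_tree_nodes(params), 1L)
  withr::with_seed(seed, {
    draws <- matrix(rnorm(nn * 4), nn, 4)
    noise <- matrix(rnorm(prod(size), sd = params$noise_sd), size[1], size[2])
    delta <- matrix(rnorm(nn * 4), nn, 4)
  })
  left <- render_vessels(size, params, grow_tree(size, params, draws), noise)
  right <- render_vessels(size, params, grow_tree(size, params, draws + a * delta), noise)
  list(left = greyscale_image(left), right = greyscale_image(right))
}
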