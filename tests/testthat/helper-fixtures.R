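# Small random integer-valued images for oracle cross-checks.
rand_img <- function(n, m, vals = 0:5) {
  matrix(sample(vals, n * m, replace = TRUE), n, m)
}

# Betti count implied by a diagram at every distinct pixel level must match
# the flood-fill/Euler oracle.
expect_oracle_agreement <- function(z) {
  pd0 <- compute_persistence(z, 0)
  pd1 <- compute_persistence(z, 1)
  for (l in sort(unique(as.vector(z)))) {
    ob <- oracle_betti(z, l)
    expect_identical(pd_betti_at(pd0, l), as.integer(ob["b0"]))
    expect_identical(pd_betti_at(pd1, l), as.integer(ob["b1"]))
  }
}

# The 3x3 ring: border pixels 0, centre 1 — one loop born at 0, filled at 1.
ring3 <- function() matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3)
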