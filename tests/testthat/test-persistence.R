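test_that("dimension-0 diagram of a 1x3 ramp matches hand enumeration", {
  pd <- compute_persistence(matrix(c(0, 2, 1), 1, 3), dim = 0)
  expect_equal(nrow(pd), 2L)
  expect_equal(pd$birth, c(0, 1))
  expect_equal(pd$death, c(2, 2))
  expect_equal(pd$essential, c(TRUE, FALSE))
})

test_that("a bright-centre ring yields one loop born at the ring level", {
  pd <- compute_persistence(ring3(), dim = 1)
  expect_equal(nrow(pd), 1L)
  expect_equal(pd$birth, 0)
  expect_equal(pd$death, 1)
  expect_false(pd$essential)
})

test_that("constant image: one component point, no loops", {
  z <- matrix(4, 5, 7)
  pd0 <- compute_persistence(z, 0)
  pd1 <- compute_persistence(z, 1)
  expect_equal(nrow(pd0), 1L)
  expect_true(pd0$essential)
  expect_equal(pd0$birth, 4)
  expect_equal(pd0$death, 4)
  expect_equal(nrow(pd1), 0L)
})

test_that("brute-force Betti oracle handles the documented cases", {
  z <- ring3()
  expect_identical(oracle_betti(z, 0), c(b0 = 1L, b1 = 1L))
  expect_identical(oracle_betti(z, 1), c(b0 = 1L, b1 = 0L))
  expect_identical(oracle_betti(z, -1), c(b0 = 0L, b1 = 0L))
  expect_identical(oracle_betti(matrix(0, 3, 3), 0), c(b0 = 1L, b1 = 0L))
  expect_error(oracle_betti(matrix(0, 101, 101), 0), "10,000")
})

test_that("diagrams agree with the oracle on random small images", {
  set.seed(4021)
  for (rep in 1:25) {
    z <- rand_img(sample(2:9, 1), sample(2:9, 1))
    expect_oracle_agreement(z)
  }
})

test_that("sublevel complexes are nested as the threshold grows", {
  set.seed(88)
  for (rep in 1:10) {
    z <- rand_img(6, 6)
    lv <- sort(unique(as.vector(z)))
    for (k in seq_len(length(lv) - 1)) {
      expect_true(all((z <= lv[k]) <= (z <= lv[k + 1])))
    }
    # at the top level the full grid is one component with no holes
    expect_identical(oracle_betti(z, max(z)), c(b0 = 1L, b1 = 0L))
  }
})

test_that("adding a constant shifts every birth and death by that constant", {
  set.seed(52)
  z <- rand_img(7, 7)
  for (k in 0:1) {
    pd <- compute_persistence(z, k)
    pds <- compute_persistence(z + 2.5, k)
    expect_equal(pds$birth, pd$birth + 2.5)
    expect_equal(pds$death, pd$death + 2.5)
  }
})

test_that("diagrams are invariant under grid reflections", {
  set.seed(53)
  z <- rand_img(6, 8)
  sorted_pairs <- function(pd) pd[order(pd$birth, pd$death), c("birth", "death")]
  for (k in 0:1) {
    ref <- sorted_pairs(compute_persistence(z, k))
    expect_equal(sorted_pairs(compute_persistence(z[nrow(z):1, ], k)), ref)
    expect_equal(sorted_pairs(compute_persistence(z[, ncol(z):1], k)), ref)
  }
})

test_that("zero-lifetime points can be kept for bookkeeping", {
  z <- matrix(4, 3, 3)
  pd <- compute_persistence(z, 0, drop_zero = FALSE)
  expect_equal(nrow(pd), 9L)          # 8 merge pairs + 1 essential
  expect_true(all(pd$death - pd$birth == 0))
  r <- rrpd(pd)
  expect_equal(sum(r$lifetime), 0)    # contributes nothing to the APF
})

test_that("diagram CSV round trip is lossless", {
  pd <- compute_persistence(ring3(), 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_diagram(pd, path)
  back <- read_diagram(path)
  expect_equal(back$birth, pd$birth)
  expect_equal(back$death, pd$death)
  expect_equal(back$dim, pd$dim)
  expect_equal(back$essential, pd$essential)
})
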