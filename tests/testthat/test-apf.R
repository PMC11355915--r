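make_apf <- function(m, value, dim = 0L, transform = "unit") {
  structure(tibble::tibble(m = m, value = value),
            class = c("reva_apf", class(tibble::tibble())),
            homology_dim = dim, side = NA_character_, transform = transform)
}

test_that("rotation and rescaling follow the mean-age/lifetime arithmetic", {
  pd <- structure(tibble::tibble(dim = 0L, birth = c(0, 1), death = c(2, 2),
                                 essential = c(TRUE, FALSE)),
                  class = c("reva_pd", class(tibble::tibble())))
  r <- rrpd(pd)
  expect_equal(r$mean_age, c(1, 1.5))
  expect_equal(r$lifetime, c(2, 1))

  empty <- pd[0, ]
  expect_equal(nrow(rrpd(empty)), 0L)

  degen <- pd[1, ]; degen$birth <- 3; degen$death <- 3
  expect_equal(rrpd(degen)$mean_age, 3)
  expect_equal(rrpd(degen)$lifetime, 0)

  inf <- pd; inf$death[1] <- Inf
  expect_error(rrpd(inf), "essential")
})

test_that("APF cumulatively sums lifetimes by mean age", {
  r <- structure(tibble::tibble(dim = 0L, mean_age = c(1, 1.5),
                                lifetime = c(2, 1)),
                 class = c("reva_rrpd", class(tibble::tibble())))
  curve <- apf_curve(r)
  expect_equal(apf_eval(curve, c(0.9, 1, 1.5, 10)), c(0, 2, 3, 3))

  empty <- apf_curve(r[0, ])
  expect_equal(apf_eval(empty, c(-1, 0, 5)), c(0, 0, 0))

  ties <- r; ties$mean_age <- c(2, 2); ties$lifetime <- c(1, 2)
  tc <- apf_curve(ties)
  expect_equal(nrow(tc), 1L)
  expect_equal(tc$value, 3)
})

test_that("APF curves are non-decreasing and end at the total lifetime sum", {
  set.seed(300)
  for (rep in 1:10) {
    z <- rand_img(6, 6)
    for (k in 0:1) {
      r <- rrpd(compute_persistence(z, k))
      curve <- apf_curve(r)
      if (nrow(curve)) {
        expect_true(all(diff(curve$value) >= 0))
        expect_equal(curve$value[nrow(curve)], sum(r$lifetime))
      }
    }
  }
})

test_that("signed supremum difference is found on the breakpoint union", {
  al <- make_apf(c(1, 1.5), c(2, 3))
  ar <- make_apf(1, 2)
  r <- reva(al, ar)
  expect_equal(r$value, -1)
  expect_equal(r$m_max, 1.5)

  # identical curves: 0 at the first breakpoint
  r0 <- reva(al, al)
  expect_equal(r0$value, 0)
  expect_equal(r0$m_max, 1)

  # swapping sides negates the value
  expect_equal(reva(ar, al)$value, 1)

  # contract violations
  expect_error(reva(make_apf(1, 1, dim = 0L), make_apf(1, 1, dim = 1L)),
               "dimension mismatch")
  expect_error(reva(make_apf(1, 1, transform = "unit"),
                    make_apf(1, 1, transform = "z")),
               "transform mismatch")
})

test_that("supremum dominates a dense probe grid and obeys the triangle bound", {
  set.seed(301)
  for (rep in 1:8) {
    zl <- rand_img(7, 7); zr <- rand_img(7, 7)
    for (k in 0:1) {
      al <- apf_curve(rrpd(compute_persistence(zl, k)))
      ar <- apf_curve(rrpd(compute_persistence(zr, k)))
      r <- reva(al, ar)
      grid <- seq(-1, max(c(al$m, ar$m, 0)) + 1, length.out = 200)
      d <- apf_eval(ar, grid) - apf_eval(al, grid)
      expect_true(all(abs(r$value) >= abs(d) - 1e-12))
      total <- sum(al$value[nrow(al)], ar$value[nrow(ar)], na.rm = TRUE)
      expect_lte(abs(r$value), total + 1e-12)
    }
  }
})

test_that("full image chain: identity, antisymmetry, lesion sensitivity", {
  img <- make_vessel_image(c(48, 48), seed = 31)
  self <- compute_reva_pair(img, img)
  expect_identical(self$reva0, 0)
  expect_identical(self$reva1, 0)
  expect_false(self$normalized)

  # add a dark lesion blob to one copy: component structure must differ
  lesion <- unclass(img)
  lesion[10:14, 30:34] <- 0.05
  r <- compute_reva_pair(img, greyscale_image(lesion))
  expect_gt(abs(r$reva0), 0)

  fwd <- compute_reva_pair(img, greyscale_image(lesion))
  rev <- compute_reva_pair(greyscale_image(lesion), img)
  expect_equal(rev$reva0, -fwd$reva0)
  expect_equal(rev$reva1, -fwd$reva1)

  expect_warning(compute_reva_pair(img, make_vessel_image(c(48, 52), seed = 31)),
                 "pre-aligned")
})
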