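test_that("vessel image generation is deterministic and leaves the RNG alone", {
  a <- make_vessel_image(c(48, 48), seed = 5)
  set.seed(1); x1 <- runif(1)
  b <- make_vessel_image(c(48, 48), seed = 5)
  set.seed(1); x2 <- runif(1)
  expect_identical(unclass(a), unclass(b))
  expect_identical(x1, x2)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("degenerate parameters give a background-plus-disc image", {
  expect_warning(img <- make_vessel_image(c(48, 48),
                                          vessel_params(depth = 0), seed = 1),
                 "degenerate")
  # only background and the brighter disc: no dark vessels
  expect_gt(min(img), 0.5)
})

test_that("generated vasculature has non-trivial sublevel topology", {
  p <- vessel_params()
  img <- make_vessel_image(c(96, 96), p, seed = 17)
  # threshold between vessel intensity and background: dark tree visible
  thr <- p$background - p$contrast / 2
  ob <- oracle_betti(img, thr)
  expect_gte(ob["b0"], 2)
})

test_that("paired generation: a = 0 is an exact copy, same seed reproduces", {
  pr0 <- make_pair(c(48, 48), a = 0, seed = 9)
  expect_identical(unclass(pr0$left), unclass(pr0$right))
  expect_identical(compute_reva_pair(pr0$left, pr0$right)$reva0, 0)

  pr1 <- make_pair(c(48, 48), a = 0.4, seed = 9)
  pr2 <- make_pair(c(48, 48), a = 0.4, seed = 9)
  expect_identical(unclass(pr1$right), unclass(pr2$right))
  expect_identical(unclass(pr1$left), unclass(pr0$left))  # left unaffected by a
  expect_false(identical(unclass(pr1$left), unclass(pr1$right)))

  expect_error(make_pair(c(48, 48), a = -1, seed = 1), ">= 0")
  expect_error(make_pair(c(8, 8), seed = 1), ">= 32")
})

test_that("cohort generator hits the configured ROH correlation", {
  coh <- simulate_cohort(cohort_config(n_subjects = 2000, seed = 101))
  expect_lt(abs(cor(coh$u, coh$roh_count) - 0.229), 0.05)

  null <- simulate_cohort(cohort_config(n_subjects = 2000, seed = 102,
                                        roh_correlation = 0))
  expect_lt(abs(cor(null$u, null$roh_count)), 0.05)

  expect_error(cohort_config(roh_correlation = 1), "strictly in")
})

test_that("zero effect sizes give pure fluctuating asymmetry", {
  coh <- simulate_cohort(cohort_config(n_subjects = 1500, seed = 103,
                                       shared_effect = 0))
  traits <- bilateral_traits()
  d <- coh[[paste0(traits$trait[1], "_left")]] -
    coh[[paste0(traits$trait[1], "_right")]]
  # mean signed residual ~ 0, sd ~ trait_noise * scale
  expect_lt(abs(mean(d)) / sd(d), 3 / sqrt(1500) * 1.5)
})

test_that("cohort simulation is deterministic and round-trips through CSV", {
  cfg <- cohort_config(n_subjects = 150, seed = 104)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(as.data.frame(c1), as.data.frame(c2))

  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(c1), tolerance = 1e-12)
  expect_identical(levels(back$cohort), levels(c1$cohort))
})

test_that("survival generation matches the configured regime", {
  coh <- simulate_cohort(cohort_config(n_subjects = 3000, seed = 105))
  expect_true(all(coh$time > 0))
  expect_gt(mean(coh$event), 0.3)
  expect_lt(mean(coh$event), 0.5)
  # hazard rises with comorbidity: more events among the comorbid
  hi <- coh$comorbidity >= 2
  expect_gt(mean(coh$event[hi]), mean(coh$event[!hi]))
})
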