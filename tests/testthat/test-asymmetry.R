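test_that("signed residuals carry the left-minus-right convention", {
  expect_equal(signed_residual(5, 5), 0)
  expect_equal(signed_residual(7, 4), 3)
  expect_equal(signed_residual(4, 7), -3)
  expect_true(is.na(signed_residual(NA, 7)))
})

test_that("max-normalization maps each trait onto [0,1] with max exactly 1", {
  df <- tibble::tibble(subject_id = letters[1:3], trait = "t",
                       group = "ophthalmic", signed = c(1, -2, 4))
  out <- normalize_trait(df)
  expect_equal(out$normalized, c(0.25, 0.5, 1))

  single <- normalize_trait(df[3, ])
  expect_equal(single$normalized, 1)

  zero <- df; zero$signed <- 0
  expect_warning(z <- normalize_trait(zero), "zero")
  expect_equal(z$normalized, c(0, 0, 0))
})

test_that("group means average normalized values and respect missingness", {
  df <- tibble::tibble(
    subject_id = c("a", "a", "a", "b", "b"),
    group = c("ophthalmic", "ophthalmic", "abpi", "ophthalmic", "abpi"),
    normalized = c(0, 1, 0.5, NA, NA))
  gm <- group_asymmetry(df)
  expect_equal(gm$group_mean[gm$subject_id == "a" & gm$group == "ophthalmic"], 0.5)
  expect_equal(gm$group_mean[gm$subject_id == "a" & gm$group == "abpi"], 0.5)
  expect_true(is.na(gm$group_mean[gm$subject_id == "b" & gm$group == "ophthalmic"]))
})

test_that("top-decile flags follow the type-7 quantile with >= tie rule", {
  gm <- tibble::tibble(subject_id = sprintf("s%02d", 1:20), group = "retina",
                       group_mean = (1:20) / 20)
  fl <- top_decile_flags(gm)
  expect_equal(sum(fl$flag), 2L)
  expect_equal(sort(fl$subject_id[fl$flag]), c("s19", "s20"))

  # monotone: raising a value never unflags anyone who was flagged
  gm2 <- gm; gm2$group_mean[19] <- 2
  fl2 <- top_decile_flags(gm2)
  expect_true(all(fl$subject_id[fl$flag] %in% fl2$subject_id[fl2$flag]))

  # degenerate all-equal group: everyone flagged, with a warning
  eq <- gm; eq$group_mean <- 0.5
  expect_warning(fle <- top_decile_flags(eq), "all-equal")
  expect_true(all(fle$flag))

  expect_error(top_decile_flags(gm[1:5, ]), ">= 10")
  expect_error(top_decile_flags(gm, frac = 1.2), "in \\(0, 1\\)")
})

test_that("overlap reproduces a brute-force Venn enumeration", {
  # all 16 flag patterns, pattern k repeated k+1 times
  pats <- expand.grid(abpi = c(FALSE, TRUE), audiometry = c(FALSE, TRUE),
                      ophthalmic = c(FALSE, TRUE), retina = c(FALSE, TRUE))
  reps <- rep(seq_len(16), times = seq_len(16))
  flags <- tibble::tibble(
    subject_id = sprintf("s%03d", seq_along(reps)),
    pat = reps) |>
    dplyr::bind_cols(pats[reps, ]) |>
    tidyr::pivot_longer(c("abpi", "audiometry", "ophthalmic", "retina"),
                        names_to = "group", values_to = "flag")
  ov <- overlap(flags)

  expect_equal(sum(ov$by_count$n), length(reps))
  # brute force by independent tabulation
  nf <- rowSums(pats[reps, ])
  expect_equal(ov$by_count$n, as.integer(table(factor(nf, levels = 0:4))))
  expect_equal(mean(nf >= 2), ov$multi_fraction)
  # each Venn region holds exactly its pattern multiplicity
  expect_equal(sort(ov$venn$n), sort(as.integer(table(reps))))
})

test_that("the full chain excludes hearing-loss subjects from audiometry only", {
  cfg <- cohort_config(n_subjects = 300, seed = 200, hearing_excl_frac = 0.2)
  coh <- simulate_cohort(cfg)
  bl <- cohort_to_bilateral(coh)
  excl <- coh$subject_id[coh$hearing_loss_excl]
  aud <- bl[bl$group == "audiometry" & bl$subject_id %in% excl, ]
  expect_true(all(is.na(aud$signed)))
  oph <- bl[bl$group == "ophthalmic" & bl$subject_id %in% excl, ]
  expect_true(all(!is.na(oph$signed)))

  ch <- asymmetry_chain(coh)
  gm <- ch$group_means
  expect_true(all(is.na(gm$group_mean[gm$group == "audiometry" &
                                        gm$subject_id %in% excl])))
  # normalized values all land in [0,1]
  expect_true(all(ch$bilateral$normalized >= 0 &
                    ch$bilateral$normalized <= 1, na.rm = TRUE))
  expect_equal(sum(ch$overlap$by_count$n), nrow(coh))
})
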