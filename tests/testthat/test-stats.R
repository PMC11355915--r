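test_that("correlation table recovers exact and configured correlations", {
  coh <- simulate_cohort(cohort_config(n_subjects = 2000, seed = 301))
  coh$u_neg <- -coh$u
  out <- correlation_matrix(coh, c("u", "u_neg", "roh_count"), against = "u")
  expect_equal(out$r_u[out$trait == "u"], 1)
  expect_equal(out$r_u[out$trait == "u_neg"], -1)
  # generator calibration surfaces through the correlation stage
  expect_lt(abs(out$r_u[out$trait == "roh_count"] - 0.229), 0.05)
  expect_true(all(out$n_u == 2000))

  coh$flat <- 1
  expect_warning(cm <- correlation_matrix(coh, "flat", against = "u"),
                 "constant")
  expect_true(is.na(cm$r_u))

  expect_error(correlation_matrix(coh, "nope", against = "u"), "not found")
  expect_error(correlation_matrix(coh[1:2, ], "roh_count", against = "u"),
               ">= 3 complete")
})

test_that("optional Benjamini-Hochberg adjustment only grows p-values", {
  coh <- simulate_cohort(cohort_config(n_subjects = 500, seed = 302))
  traits <- c("roh_count", "roh_total_kb", "roh_avg_kb")
  raw <- correlation_matrix(coh, traits, against = "u")
  adj <- correlation_matrix(coh, traits, against = "u", adjust = "BH")
  expect_true(all(adj$p_u >= raw$p_u - 1e-15))
  expect_equal(adj$r_u, raw$r_u)
})

test_that("Cox fit honours reference levels and rank invariance", {
  coh <- simulate_cohort(cohort_config(n_subjects = 800, seed = 303))
  fit <- cox_fit(coh, c("age", "sex", "cohort", "comorbidity"))
  td <- tidy(fit)
  expect_true(all(c("sexwomen", "cohortKorcula", "cohortSplit") %in% td$term))
  expect_false(any(grepl("sexmen|cohortVis", td$term)))

  # doubling all times with events fixed leaves hazard ratios unchanged
  coh2 <- coh; coh2$time <- coh2$time * 2
  td2 <- tidy(cox_fit(coh2, c("age", "sex", "cohort", "comorbidity")))
  expect_equal(td2$hr, td$hr, tolerance = 1e-8)

  gl <- glance(fit)
  expect_equal(gl$n_events, sum(coh$event))
  expect_gt(gl$concordance, 0.5)

  # unadjusted variant: one model per covariate
  un <- cox_fit(coh, c("age", "comorbidity"), adjusted = FALSE)
  expect_equal(sort(unique(tidy(un)$model)), c("age", "comorbidity"))

  few <- coh[coh$event == 1, ][1:5, ]
  expect_error(cox_fit(few, "age"), ">= 10 events")
})

test_that("group tests dispatch t-test, ANOVA and chi-square correctly", {
  coh <- simulate_cohort(cohort_config(n_subjects = 400, seed = 304))
  tt <- group_tests(coh, "age", "sex")
  expect_equal(tt$test, "t-test")
  av <- group_tests(coh, "age", "cohort")
  expect_equal(av$test, "anova")
  coh$comorb_any <- factor(coh$comorbidity > 0)
  ch <- group_tests(coh, "comorb_any", "sex")
  expect_equal(ch$test, "chi-square")
  expect_true(all(c(tt$p_value, av$p_value, ch$p_value) >= 0))

  # identical groups: |t| ~ 0 and chi-square statistic 0
  df <- tibble::tibble(x = rep(rnorm(50, sd = 2), 2),
                       g = rep(c("a", "b"), each = 50))
  expect_lt(abs(group_tests(df, "x", "g")$statistic), 1e-10)
  df$cat <- factor(rep(rep(c("u", "v"), 25), 2))
  expect_lt(group_tests(df, "cat", "g")$statistic, 1e-10)

  expect_error(group_tests(coh, "age", "nope"), "not found")
})
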