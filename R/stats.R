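#' Pairwise Pearson correlations against the retinal asymmetry scores
#'
#' For each requested trait column, computes the Pearson correlation (and
#' two-sided p-value) with each score column, using pairwise-complete
#' observations — the layout of a correlation selection table with one row
#' per trait and an `r (p)` pair per score. A constant series yields missing
#' `r` with a warning. No multiple-testing correction is applied by default;
#' `adjust = "BH"` switches on Benjamini-Hochberg within each score column.
#'
#' @param cohort A data frame of per-subject values.
#' @param traits Character vector of trait column names.
#' @param against Character vector of score columns (default `reva0`,
#'   `reva1`).
#' @param adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return A tibble with columns `trait` and, per score, `r_<score>`,
#'   `p_<score>`, `n_<score>`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 300, seed = 9))
#' correlation_matrix(coh, c("roh_count", "roh_total_kb"))
#' @export
correlation_matrix <- function(cohort, traits, against = c("reva0", "reva1"),
                               adjust = "none") {
  missing_cols <- setdiff(c(traits, against), names(cohort))
  if (length(missing_cols))
    abort(sprintf("columns not found: %s", paste(missing_cols, collapse = ", ")))
  one <- function(trait, score) {
    x <- cohort[[trait]]; y <- cohort[[score]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3L)
      abort(sprintf("need >= 3 complete pairs for %s vs %s (have %d).",
                    trait, score, n))
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      warn(sprintf("constant series in %s vs %s; correlation undefined.",
                   trait, score))
      return(tibble(r = NA_real_, p = NA_real_, n = n))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
  }
  out <- purrr::map(against, function(score) {
    res <- purrr::map(traits, one, score = score) |> dplyr::bind_rows()
    if (!identical(adjust, "none")) res$p <- stats::p.adjust(res$p, adjust)
    names(res) <- paste0(c("r_", "p_", "n_"), score)
    res
  }) |> dplyr::bind_cols()
  dplyr::bind_cols(tibble(trait = traits), out)
}

#' Cox proportional-hazards fit with the study's reporting contract
#'
#' Fits `survival::coxph()` on a cohort table, either unadjusted (each
#' covariate alone) or adjusted (all covariates jointly). Reference levels
#' follow the study design: men, the `Vis` sub-cohort and no multiple
#' asymmetries are the baselines. Requires at least 10 events.
#'
#' @param records Data frame with `time`, `event` and the covariates.
#' @param covariates Character vector of covariate columns.
#' @param adjusted Joint model (`TRUE`, default) or one single-covariate
#'   model per term (`FALSE`).
#' @return An object of class `reva_cox` wrapping the fit(s); use [tidy()]
#'   for hazard ratios with 95% CIs and p-values, [glance()] for model-level
#'   summaries.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 400, seed = 5))
#' fit <- cox_fit(coh, c("age", "sex", "comorbidity"))
#' tidy(fit)
#' @export
cox_fit <- function(records, covariates, adjusted = TRUE) {
  missing_cols <- setdiff(c("time", "event", covariates), names(records))
  if (length(missing_cols))
    abort(sprintf("columns not found: %s", paste(missing_cols, collapse = ", ")))
  df <- records[c("time", "event", covariates)]
  complete <- complete.cases(df)
  n_dropped <- sum(!complete)
  df <- df[complete, ]
  if (sum(df$event) < 10L)
    abort(sprintf("need >= 10 events to fit (have %d).", sum(df$event)))
  if ("sex" %in% names(df)) df$sex <- stats::relevel(factor(df$sex), "men")
  if ("cohort" %in% names(df)) df$cohort <- stats::relevel(factor(df$cohort), "Vis")
  if ("multi_asymmetry" %in% names(df))
    df$multi_asymmetry <- factor(df$multi_asymmetry, levels = c(FALSE, TRUE),
                                 labels = c("no", "yes"))
  fit_one <- function(terms) {
    f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
    fit <- survival::coxph(f, data = df)
    if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0))
      abort("Cox fit failed to converge.")
    fit
  }
  fits <- if (adjusted) list(joint = fit_one(covariates))
          else setNames(lapply(covariates, fit_one), covariates)
  structure(list(fits = fits, adjusted = adjusted, covariates = covariates,
                 n = nrow(df), n_events = sum(df$event), n_dropped = n_dropped),
            class = "reva_cox")
}

#' @export
print.reva_cox <- function(x, ...) {
  cat(sprintf("<reva_cox> %s model, %d subjects (%d dropped), %d events\n",
              if (x$adjusted) "adjusted" else "unadjusted",
              x$n, x$n_dropped, x$n_events))
  print(tidy(x))
  invisible(x)
}

#' @rdname cox_fit
#' @param x A `reva_cox` object.
#' @param ... Unused.
#' @export
tidy.reva_cox <- function(x, ...) {
  purrr::imap(x$fits, function(fit, label) {
    s <- summary(fit)
    tibble(model = label,
           term = rownames(s$coefficients),
           estimate = s$coefficients[, "coef"],
           hr = s$conf.int[, "exp(coef)"],
           conf_low = s$conf.int[, "lower .95"],
           conf_high = s$conf.int[, "upper .95"],
           p_value = s$coefficients[, "Pr(>|z|)"])
  }) |> dplyr::bind_rows()
}

#' @rdname cox_fit
#' @export
glance.reva_cox <- function(x, ...) {
  purrr::imap(x$fits, function(fit, label) {
    s <- summary(fit)
    tibble(model = label, n = x$n, n_events = x$n_events,
           concordance = unname(s$concordance["C"]),
           logtest_p = unname(s$logtest["pvalue"]))
  }) |> dplyr::bind_rows()
}

#' Bivariate group comparisons
#'
#' The standard battery for a demographics table: Welch t-test for a numeric
#' variable across two groups, one-way ANOVA across three or more, and the
#' chi-square test for a categorical variable, each two-sided via the base R
#' routine.
#'
#' @param cohort Data frame.
#' @param var Column to test.
#' @param by Grouping column (categorical).
#' @return A one-row tibble: `variable`, `by`, `test`, `statistic`,
#'   `p_value`, `df`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 300, seed = 2))
#' group_tests(coh, "age", "cohort")
#' @export
group_tests <- function(cohort, var, by) {
  missing_cols <- setdiff(c(var, by), names(cohort))
  if (length(missing_cols))
    abort(sprintf("columns not found: %s", paste(missing_cols, collapse = ", ")))
  g <- factor(cohort[[by]])
  x <- cohort[[var]]
  sizes <- table(g[!is.na(x)])
  if (any(sizes == 0))
    abort(sprintf("empty group '%s' for variable '%s'.",
                  names(sizes)[sizes == 0][1], var))
  if (is.numeric(x)) {
    if (nlevels(g) == 2L) {
      tt <- t.test(x ~ g)
      tibble(variable = var, by = by, test = "t-test",
             statistic = unname(tt$statistic), p_value = tt$p.value,
             df = unname(tt$parameter))
    } else {
      av <- summary(aov(x ~ g))[[1]]
      tibble(variable = var, by = by, test = "anova",
             statistic = av$`F value`[1], p_value = av$`Pr(>F)`[1],
             df = av$Df[1])
    }
  } else {
    tab <- table(factor(cohort[[var]]), g)
    ch <- suppressWarnings(chisq.test(tab))
    tibble(variable = var, by = by, test = "chi-square",
           statistic = unname(ch$statistic), p_value = ch$p.value,
           df = unname(ch$parameter))
  }
}
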