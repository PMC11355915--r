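#' Pivot a cohort table into long bilateral form
#'
#' One row per subject x trait with `left`/`right` columns, plus two
#' `retina` rows per subject carrying the signed `reva0`/`reva1` scores in
#' the `signed` column (a retinal asymmetry score is already a left-right
#' contrast, so it enters the chain at the residual stage). Subjects flagged
#' for unilateral hearing loss have their audiometry rows set to missing —
#' they are excluded from that group only.
#'
#' @param cohort A tibble from [simulate_cohort()] (or with the same
#'   `<trait>_left`/`<trait>_right` layout plus `reva0`, `reva1`).
#' @return A tibble with columns `subject_id`, `trait`, `group`, `left`,
#'   `right`, `signed`.
#' @export
cohort_to_bilateral <- function(cohort) {
  traits <- bilateral_traits()
  long <- cohort |>
    dplyr::select("subject_id", "hearing_loss_excl",
                  dplyr::matches("_(left|right)$")) |>
    tidyr::pivot_longer(dplyr::matches("_(left|right)$"),
                        names_to = c("trait", "side"),
                        names_pattern = "^(.*)_(left|right)$") |>
    tidyr::pivot_wider(names_from = "side", values_from = "value") |>
    dplyr::left_join(traits[, c("trait", "group")], by = "trait") |>
    dplyr::mutate(
      left = ifelse(.data$group == "audiometry" & .data$hearing_loss_excl,
                    NA_real_, .data$left),
      right = ifelse(.data$group == "audiometry" & .data$hearing_loss_excl,
                     NA_real_, .data$right),
      signed = signed_residual(.data$left, .data$right)) |>
    dplyr::select("subject_id", "trait", "group", "left", "right", "signed")

  retina <- cohort |>
    dplyr::select("subject_id", reva0 = "reva0", reva1 = "reva1") |>
    tidyr::pivot_longer(c("reva0", "reva1"),
                        names_to = "trait", values_to = "signed") |>
    dplyr::mutate(group = "retina", left = NA_real_, right = NA_real_) |>
    dplyr::select("subject_id", "trait", "group", "left", "right", "signed")

  dplyr::bind_rows(long, retina) |>
    dplyr::arrange(.data$subject_id, .data$group, .data$trait)
}

#' Signed left-right residual
#'
#' The signed asymmetry of one bilateral measurement, `left - right`. Under
#' fluctuating asymmetry these residuals average to zero across a
#' population; directional asymmetry shows as a consistent sign.
#'
#' @param left,right Numeric vectors; a missing side yields a missing
#'   residual (excluded downstream).
#' @return `left - right`.
#' @examples
#' signed_residual(7, 4)
#' @export
signed_residual <- function(left, right) left - right

#' Max-normalize absolute residuals within each trait
#'
#' Divides each trait's absolute residuals by the trait maximum over
#' subjects, giving unitless values in \[0, 1\] that can be averaged across
#' traits: the subject with the largest asymmetry for a trait scores exactly
#' 1. An all-zero trait is left at zero with a warning.
#'
#' @param bilateral Long tibble from [cohort_to_bilateral()] (needs `trait`
#'   and `signed`).
#' @return The input with `absolute` and `normalized` columns added.
#' @examples
#' df <- tibble::tibble(subject_id = c("a", "b", "c"), trait = "t",
#'                      group = "ophthalmic", signed = c(1, -2, 4))
#' normalize_trait(df)$normalized
#' @export
normalize_trait <- function(bilateral) {
  out <- bilateral |>
    dplyr::mutate(absolute = abs(.data$signed)) |>
    dplyr::group_by(.data$trait) |>
    dplyr::mutate(.max = max(.data$absolute, na.rm = TRUE),
                  normalized = dplyr::case_when(
                    is.na(.data$absolute) ~ NA_real_,
                    .data$.max > 0 ~ .data$absolute / .data$.max,
                    TRUE ~ 0)) |>
    dplyr::ungroup()
  zero_traits <- unique(out$trait[out$.max == 0 & !is.na(out$.max)])
  if (length(zero_traits))
    warn(sprintf("all residuals are zero for trait(s): %s; normalized values set to 0.",
                 paste(zero_traits, collapse = ", ")))
  dplyr::select(out, -".max")
}

#' Per-subject mean asymmetry by body-part group
#'
#' Averages the normalized asymmetries within each of the four groups
#' (retina, ophthalmic, abpi, audiometry) per subject. A subject with no
#' non-missing trait in a group gets a missing group mean.
#'
#' @param normalized Tibble from [normalize_trait()].
#' @return A tibble `subject_id`, `group`, `group_mean` (values in \[0, 1\]).
#' @export
group_asymmetry <- function(normalized) {
  normalized |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::summarise(
      group_mean = if (all(is.na(.data$normalized))) NA_real_
                   else mean(.data$normalized, na.rm = TRUE),
      .groups = "drop")
}

#' Flag the most asymmetric decile per group
#'
#' Within each group, flags subjects whose group mean is at or above the
#' empirical `1 - frac` quantile (type-7, the R default); ties at the
#' threshold are all flagged, so the rule is deterministic and
#' order-independent. Requires at least 10 non-missing subjects per group.
#' If a group's values are all equal the quantile is degenerate: everyone is
#' flagged, with a warning.
#'
#' @param group_means Tibble from [group_asymmetry()].
#' @param frac Upper tail fraction to flag (default 0.10).
#' @return The input with `threshold` and logical `flag` columns.
#' @export
top_decile_flags <- function(group_means, frac = 0.10) {
  if (frac <= 0 || frac >= 1) abort("`frac` must be in (0, 1).")
  counts <- group_means |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_ok = sum(!is.na(.data$group_mean)), .groups = "drop")
  bad <- counts$group[counts$n_ok < 10]
  if (length(bad))
    abort(sprintf("need >= 10 subjects with a group mean to classify; too few in: %s",
                  paste(bad, collapse = ", ")))
  out <- group_means |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(threshold = quantile(.data$group_mean, 1 - frac,
                                       na.rm = TRUE, type = 7),
                  flag = .data$group_mean >= .data$threshold) |>
    dplyr::ungroup()
  degen <- out |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(all_eq = dplyr::n_distinct(.data$group_mean[!is.na(.data$group_mean)]) == 1L,
                     .groups = "drop")
  if (any(degen$all_eq))
    warn(sprintf("group(s) with all-equal asymmetry: %s; every subject flagged.",
                 paste(degen$group[degen$all_eq], collapse = ", ")))
  out
}

#' Multi-asymmetry overlap across the four body parts
#'
#' Cross-tabulates the per-group top-decile flags into the full 4-set Venn
#' partition, counts subjects by number of flags (0-4), and marks subjects
#' with two or more flags as multiple-asymmetry cases. A missing flag
#' (subject not classifiable in a group) counts as not flagged but is
#' recorded.
#'
#' @param flags Tibble from [top_decile_flags()].
#' @return A list of class `reva_overlap`: `per_subject` (subject_id, one
#'   logical column per group, `n_flags`, `multi_asymmetry`), `by_count`
#'   (0-4 flag counts), `venn` (all 16 regions), `n_subjects`,
#'   `multi_fraction`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 200, seed = 3))
#' ov <- coh |> cohort_to_bilateral() |> normalize_trait() |>
#'   group_asymmetry() |> top_decile_flags() |> overlap()
#' ov$by_count
#' @export
overlap <- function(flags) {
  groups <- sort(unique(flags$group))
  wide <- flags |>
    dplyr::select("subject_id", "group", "flag") |>
    tidyr::pivot_wider(names_from = "group", values_from = "flag")
  miss <- setdiff(groups, names(wide))
  if (length(miss))
    abort(sprintf("missing flag column(s): %s", paste(miss, collapse = ", ")))
  incomplete <- wide$subject_id[!complete.cases(wide[groups])]
  per_subject <- wide |>
    dplyr::mutate(dplyr::across(dplyr::all_of(groups), ~ !is.na(.x) & .x)) |>
    dplyr::mutate(n_flags = rowSums(dplyr::pick(dplyr::all_of(groups))),
                  multi_asymmetry = .data$n_flags >= 2)
  by_count <- tibble(n_flags = 0:length(groups)) |>
    dplyr::left_join(dplyr::count(per_subject, .data$n_flags),
                     by = "n_flags") |>
    tidyr::replace_na(list(n = 0L))
  venn <- per_subject |>
    dplyr::count(dplyr::across(dplyr::all_of(groups)), name = "n") |>
    tidyr::complete(!!!rlang::syms(groups), fill = list(n = 0L)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(groups)))
  structure(list(per_subject = per_subject, by_count = by_count, venn = venn,
                 n_subjects = nrow(per_subject),
                 n_incomplete = length(incomplete),
                 multi_fraction = mean(per_subject$multi_asymmetry)),
            class = "reva_overlap")
}

#' @export
print.reva_overlap <- function(x, ...) {
  cat(sprintf("<reva_overlap> %d subjects (%d with an unclassifiable group)\n",
              x$n_subjects, x$n_incomplete))
  cat(sprintf("  multiple asymmetries (>= 2 flags): %d (%.1f%%)\n",
              sum(x$per_subject$multi_asymmetry), 100 * x$multi_fraction))
  print(x$by_count)
  invisible(x)
}

#' Run the full asymmetry chain on a cohort table
#'
#' Convenience wrapper: [cohort_to_bilateral()] into [normalize_trait()]
#' into [group_asymmetry()] into [top_decile_flags()] into [overlap()],
#' returning all intermediate tables.
#'
#' @inheritParams cohort_to_bilateral
#' @inheritParams top_decile_flags
#' @return A list with `bilateral`, `group_means`, `flags`, `overlap`.
#' @export
asymmetry_chain <- function(cohort, frac = 0.10) {
  bilateral <- normalize_trait(cohort_to_bilateral(cohort))
  group_means <- group_asymmetry(bilateral)
  flags <- top_decile_flags(group_means, frac = frac)
  list(bilateral = bilateral, group_means = group_means, flags = flags,
       overlap = overlap(flags))
}
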