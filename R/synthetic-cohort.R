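#' Configuration of the synthetic cohort generator
#'
#' Defines the study conditions the simulator emulates: a three-sub-cohort
#' population (two island isolates and one mainland city, weighted 617 : 470 :
#' 786), 39.5% men, twenty bilateral traits (nine ophthalmic, three
#' ankle-brachial pressure measurements, eight audiometric frequencies), a
#' latent per-subject asymmetry propensity shared across traits,
#' runs-of-homozygosity summaries positively correlated with that propensity,
#' and censored survival times from a proportional-hazards model with age,
#' sex and comorbidity effects.
#'
#' The propensity `u` is log-normal; each trait's signed left-right
#' difference is `shared_effect * group effect * trait scale * u * N(0,1)`
#' plus independent measurement noise, split symmetrically about the trait's
#' base value, so residuals fluctuate around zero. Setting
#' `shared_effect = 0` gives the regime in which asymmetries in different
#' body parts are independent. The Poisson rate for the ROH segment count is
#' linear in `u` with slope `r * sqrt(mean_count / (1 - r^2)) / sd(u)`, which
#' makes the correlation between `u` and the count equal the target `r` in
#' expectation — a closed-form calibration, not a fitted one.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @param sigma_u Log-scale SD of the latent asymmetry propensity.
#' @param shared_effect Strength of the shared propensity across body parts;
#'   0 = independent asymmetries.
#' @param effect_retina,effect_ophthalmic,effect_abpi,effect_audiometry
#'   Per-group effect multipliers.
#' @param trait_noise Measurement-noise multiplier (per trait scale).
#' @param roh_correlation Target Pearson correlation between the latent
#'   propensity and the ROH segment count, in (-1, 1).
#' @param roh_mean_count,roh_mean_seg_kb Mean ROH segment count and mean
#'   segment length (kb).
#' @param cohort_weights Named sampling weights for the three sub-cohorts.
#' @param p_female Probability of female sex.
#' @param hearing_excl_frac Fraction flagged for unilateral hearing loss and
#'   excluded from the audiometry group.
#' @param baseline_hazard Exponential baseline hazard per year.
#' @param loghr_age,loghr_female,loghr_comorbidity True log hazard ratios.
#' @param censor_frac Approximate fraction censored.
#' @return A named list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 500, seed = 1,
                          sigma_u = 0.4, shared_effect = 1,
                          effect_retina = 1, effect_ophthalmic = 1,
                          effect_abpi = 1, effect_audiometry = 1,
                          trait_noise = 0.6,
                          roh_correlation = 0.229,
                          roh_mean_count = 30, roh_mean_seg_kb = 1500,
                          cohort_weights = c(Vis = 617, Korcula = 470, Split = 786),
                          p_female = 0.605,
                          hearing_excl_frac = 59 / 1873,
                          baseline_hazard = 0.004,
                          loghr_age = log(1.10), loghr_female = log(0.53),
                          loghr_comorbidity = log(1.20),
                          censor_frac = 0.6) {
  cfg <- as.list(environment())
  if (cfg$n_subjects < 1) abort("`n_subjects` must be >= 1.")
  if (abs(cfg$roh_correlation) >= 1)
    abort("`roh_correlation` must lie strictly in (-1, 1).")
  if (cfg$sigma_u <= 0) abort("`sigma_u` must be positive.")
  if (cfg$censor_frac <= 0 || cfg$censor_frac >= 1)
    abort("`censor_frac` must lie in (0, 1).")
  structure(cfg, class = "cohort_config")
}

#' The bilateral trait battery
#'
#' Trait names, body-part groups, base values and measurement scales used by
#' [simulate_cohort()]: nine ophthalmic measurements (keratometry,
#' autorefraction and A-scan biometry), three Doppler systolic pressures and
#' eight pure-tone audiometry thresholds.
#'
#' @return A tibble with columns `trait`, `group`, `base`, `scale`, `units`.
#' @export
bilateral_traits <- function() {
  tibble::tribble(
    ~trait,                   ~group,        ~base,  ~scale, ~units,
    "spheric_power",          "ophthalmic",   0.25,   1.20, "D",
    "cylinder_power",         "ophthalmic",  -0.50,   0.60, "D",
    "angle",                  "ophthalmic",  90.0,   35.0,  "deg",
    "corneal_radius",         "ophthalmic",   7.8,    0.25, "mm",
    "corneal_thickness",      "ophthalmic", 545.0,   30.0,  "um",
    "anterior_chamber_length","ophthalmic",   3.1,    0.35, "mm",
    "lens_thickness",         "ophthalmic",   4.5,    0.40, "mm",
    "posterior_chamber_length","ophthalmic", 15.9,    0.80, "mm",
    "axial_length",           "ophthalmic",  23.5,    0.90, "mm",
    "abpi_radial",            "abpi",       130.0,   12.0,  "mmHg",
    "abpi_posterior_tibial",  "abpi",       135.0,   14.0,  "mmHg",
    "abpi_dorsal_foot",       "abpi",       133.0,   14.0,  "mmHg",
    "aud_250hz",              "audiometry",  15.0,    8.0,  "dB",
    "aud_500hz",              "audiometry",  14.0,    8.0,  "dB",
    "aud_1khz",               "audiometry",  14.0,    8.0,  "dB",
    "aud_2khz",               "audiometry",  15.0,    9.0,  "dB",
    "aud_3khz",               "audiometry",  17.0,   10.0,  "dB",
    "aud_4khz",               "audiometry",  20.0,   11.0,  "dB",
    "aud_6khz",               "audiometry",  24.0,   12.0,  "dB",
    "aud_8khz",               "audiometry",  28.0,   13.0,  "dB")
}

lognormal_moments <- function(sigma) {
  m <- exp(sigma^2 / 2)
  list(mean = m, sd = sqrt((exp(sigma^2) - 1)) * m)
}

#' Simulate a full cohort table
#'
#' Generates one row per subject: demographics, the latent asymmetry
#' propensity `u`, signed retinal asymmetry scores (`reva0`, `reva1`,
#' strongly mutually correlated, as the two homology dimensions of one
#' vasculature are), left and right values for all twenty bilateral traits
#' (columns `<trait>_left` / `<trait>_right`), ROH summaries and a censored
#' survival record.
#'
#' @param config A [cohort_config()].
#' @return A tibble of class `reva_cohort`, one row per subject.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 100, seed = 42))
#' dplyr::glimpse(coh[, 1:10])
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a cohort_config().")
  n <- config$n_subjects
  traits <- bilateral_traits()

  withr::with_seed(config$seed, {
    cohort <- sample(names(config$cohort_weights), n, replace = TRUE,
                     prob = config$cohort_weights)
    age_mean <- c(Vis = 55.6, Korcula = 54.5, Split = 51.0)[cohort]
    age_sd <- c(Vis = 14.2, Korcula = 15.6, Split = 14.1)[cohort]
    age <- pmax(18, pmin(95, rnorm(n, age_mean, age_sd)))
    sex <- ifelse(runif(n) < config$p_female, "women", "men")
    comorbidity <- rbinom(n, 5, stats::plogis(-1.9 + 0.02 * (age - 53)))
    u <- rlnorm(n, 0, config$sigma_u)
    hearing_loss_excl <- runif(n) < config$hearing_excl_frac

    # retina: two strongly correlated signed scores driven by u
    z0 <- rnorm(n)
    z1 <- 0.97 * z0 + sqrt(1 - 0.97^2) * rnorm(n)
    amp <- config$shared_effect * config$effect_retina
    reva0 <- amp * u * z0 * 0.25 + 0.05 * rnorm(n)
    reva1 <- amp * u * z1 * 0.25 + 0.05 * rnorm(n)

    grp_effect <- c(ophthalmic = config$effect_ophthalmic,
                    abpi = config$effect_abpi,
                    audiometry = config$effect_audiometry)
    trait_cols <- purrr::pmap(traits, function(trait, group, base, scale, units) {
      d <- config$shared_effect * grp_effect[[group]] * scale * u * rnorm(n) +
        config$trait_noise * scale * rnorm(n)
      out <- tibble(base + d / 2, base - d / 2)
      names(out) <- paste0(trait, c("_left", "_right"))
      out
    }) |> dplyr::bind_cols()

    # ROH: Poisson rate linear in u, slope from the closed-form calibration
    lm_u <- lognormal_moments(config$sigma_u)
    r <- config$roh_correlation
    b <- r * sqrt(config$roh_mean_count / (1 - r^2)) / lm_u$sd
    mu0 <- config$roh_mean_count - b * lm_u$mean
    rate <- pmax(mu0 + b * u, 1e-8)
    if (mean(rate <= 1e-8) > 0.01)
      abort("`roh_correlation` target is infeasible for this propensity distribution.")
    roh_count <- rpois(n, rate)
    roh_total_kb <- ifelse(roh_count > 0,
                           rgamma(n, shape = 2 * pmax(roh_count, 1),
                                  scale = config$roh_mean_seg_kb / 2),
                           0)
    roh_avg_kb <- ifelse(roh_count > 0, roh_total_kb / roh_count, 0)

    # survival: exponential baseline, independent exponential censoring
    lp <- config$loghr_age * (age - 53) +
      config$loghr_female * (sex == "women") +
      config$loghr_comorbidity * comorbidity
    h <- config$baseline_hazard * exp(lp)
    t_event <- rexp(n, rate = h)
    h_cens <- config$baseline_hazard * exp(mean(lp)) *
      config$censor_frac / (1 - config$censor_frac)
    t_cens <- rexp(n, rate = h_cens)
    time <- pmax(pmin(t_event, t_cens), 1e-3)
    event <- as.integer(t_event <= t_cens)
  })

  out <- dplyr::bind_cols(
    tibble(subject_id = sprintf("S%05d", seq_len(n)),
           cohort = factor(cohort, levels = names(config$cohort_weights)),
           sex = factor(sex, levels = c("men", "women")),
           age = age, comorbidity = comorbidity,
           hearing_loss_excl = hearing_loss_excl,
           u = u, reva0 = reva0, reva1 = reva1),
    trait_cols,
    tibble(roh_count = roh_count, roh_total_kb = roh_total_kb,
           roh_avg_kb = roh_avg_kb, time = time, event = event))
  structure(out, class = c("reva_cohort", class(tibble())))
}

#' Write or read a cohort table as CSV
#'
#' Round-trips losslessly: factor levels for `cohort` and `sex` are restored
#' on read.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param path CSV path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  attr(x, "spec") <- NULL
  attr(x, "problems") <- NULL
  if ("cohort" %in% names(x))
    x$cohort <- factor(x$cohort, levels = unique(c("Vis", "Korcula", "Split", x$cohort)))
  if ("sex" %in% names(x)) x$sex <- factor(x$sex, levels = c("men", "women"))
  structure(x, class = c("reva_cohort", class(tibble())))
}
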