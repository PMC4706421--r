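#' Configuration for the synthetic cohort generator
#'
#' Describes a mixed-age, two-sex, obesity-enriched clinical cohort in which
#' a single latent severity factor drives the correlation between the
#' metabolic syndrome components — the structure that makes z-sum and PCA
#' comparator scores meaningful. Demographic defaults (sex ratio, three-group
#' age mixture) follow the published descriptives of a typical
#' endocrinology-clinic validation sample: 34.5\% male; children, young
#' adults and adults mixed 13.8/30.5/55.7\% with mean ages 13.2, 24.3 and
#' 48.2 years (sd 2.8, 3.4, 10.6), ages clamped to 7-77. Component-level
#' means, slopes and loadings are package calibration artifacts (see
#' `scripts/calibrate_synthetic.R`), tuned once so the generated cohorts are
#' obesity-enriched (mean BMI near 32 kg/m2) with a dichotomous metabolic
#' syndrome prevalence near 47\%.
#'
#' @param n Number of subjects.
#' @param seed Integer RNG seed; generation is fully deterministic given
#'   the config.
#' @param sex_ratio_male Fraction of male subjects.
#' @param age_weights,age_means,age_sds Three-group age mixture (children /
#'   young adults / adults); weights must sum to 1.
#' @param age_range Ages are clamped to this interval (years).
#' @param severity_scale Multiplier on every latent-severity loading;
#'   1 reproduces the calibrated defaults, larger values make components
#'   more strongly correlated and the cohort sicker.
#' @param lipid_axis_scale Multiplier on the lipid-specific latent factor
#'   that couples triglycerides and HDL beyond the general severity axis.
#'   At the default 1, a correlation-matrix PCA of the five syndrome
#'   components extracts two factors (general severity plus a lipid axis);
#'   at 0 the generator reduces to a single latent severity factor and only
#'   one factor is extracted, emulating the structure of age-homogeneous
#'   subsamples.
#' @param family_history_prevalence Bernoulli rate of positive family
#'   history of cardio/cerebro-vascular events.
#' @param missingness Named numeric vector of per-field missingness rates in
#'   [0, 1]; names among the cohort columns (e.g. `c(hdl = 0.05)`). Applied
#'   independently per field, after generation. Default: none.
#' @return Object of class `synthetic_cohort_config`.
#' @examples
#' cfg <- synthetic_config(n = 100, seed = 42)
#' cohort <- generate_cohort(cfg)
#' @export
synthetic_config <- function(n = 528,
                             seed = 1,
                             sex_ratio_male = 0.345,
                             age_weights = c(0.138, 0.305, 0.557),
                             age_means = c(13.2, 24.3, 48.2),
                             age_sds = c(2.8, 3.4, 10.6),
                             age_range = c(7, 77),
                             severity_scale = 1,
                             lipid_axis_scale = 1,
                             family_history_prevalence = 0.3,
                             missingness = numeric(0)) {
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != floor(n)) {
    stop("n must be a non-negative integer.", call. = FALSE)
  }
  if (abs(sum(age_weights) - 1) > 1e-8) {
    stop("age_weights must sum to 1.", call. = FALSE)
  }
  stopifnot(length(age_weights) == 3, length(age_means) == 3,
            length(age_sds) == 3, all(age_sds > 0),
            sex_ratio_male >= 0, sex_ratio_male <= 1,
            family_history_prevalence >= 0, family_history_prevalence <= 1,
            severity_scale > 0, lipid_axis_scale >= 0,
            length(age_range) == 2,
            age_range[1] < age_range[2])
  if (length(missingness) > 0) {
    bad <- setdiff(names(missingness),
                   c(cohort_numeric_columns(), "family_history_cv"))
    if (length(bad) > 0 || is.null(names(missingness))) {
      stop("missingness names must be cohort fields (offending: ",
           paste(bad, collapse = ", "), ").", call. = FALSE)
    }
    stopifnot(all(missingness >= 0), all(missingness <= 1))
  }
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    sex_ratio_male = sex_ratio_male,
    age_weights = age_weights, age_means = age_means, age_sds = age_sds,
    age_range = age_range, severity_scale = severity_scale,
    lipid_axis_scale = lipid_axis_scale,
    family_history_prevalence = family_history_prevalence,
    missingness = missingness
  ), class = "synthetic_cohort_config")
}

# Calibrated component model (modelling scale; log scale for Tg and
# insulin). Values are package calibration artifacts produced by
# scripts/calibrate_synthetic.R, not measured population parameters.
synthetic_component_model <- function() {
  list(
    sbp = list(mean = 122, age = 0.35, male = 4, load = 7, noise = 8),
    dbp_gap = list(mean = 40, noise = 7, min = 5),
    log_tg = list(mean = log(1.55), age = 0.004, male = 0.08, load = 0.15,
                  lipid = 0.35, noise = 0.16),
    hdl = list(mean = 1.32, age = 0, male = -0.20, load = -0.105,
               lipid = -0.175, noise = 0.12, min = 0.4),
    glucose = list(mean = 5.35, age = 0.012, male = 0.05, load = 0.45,
                   noise = 0.55, min = 3),
    log_insulin = list(mean = log(11), age = 0, male = 0, load = 0.35,
                       noise = 0.45),
    whtr = list(mean = 0.565, age = 0.0012, male = 0.010, load = 0.055,
                noise = 0.045, min = 0.35),
    bmi = list(mean = 31, age = 0.05, male = 0, load = 2.8, noise = 4,
               min = 15),
    height = list(male_mean = 177, male_sd = 7, female_mean = 164,
                  female_sd = 6.5)
  )
}

# Height growth fraction: linear approach to adult stature by age 16.
growth_fraction <- function(age) pmin(1, 0.45 + 0.55 * age / 16)

#' Generate a synthetic clinical cohort
#'
#' Draws sex and age from the configured mixture, a standard-normal latent
#' severity per subject (plus a second, lipid-specific latent factor, see
#' [synthetic_config()]), and each metabolic syndrome component as
#' mean + age slope + sex effect + factor loadings + independent noise on
#' its modelling scale (log for triglycerides and insulin, so both are
#' strictly positive). Height is drawn by sex with a growth curve for
#' children; waist derives from a severity-dependent waist-to-height ratio;
#' weight derives from a severity-dependent BMI; diastolic pressure is
#' systolic minus a positive gap (so SBP > DBP always). Treatment flags are
#' all negative — the generator emulates an untreated scoring population.
#' Missingness, if configured, is applied independently per field as the
#' last step. Fully deterministic given the config (including its seed).
#'
#' @param cfg A [synthetic_config()].
#' @return A `sims_cohort` of `cfg$n` subjects, with attribute
#'   `latent_severity` carrying the generating severity draws (for tests
#'   and calibration, not a clinical field).
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  n <- cfg$n
  if (n == 0) {
    empty <- as_cohort(data.frame(subject_id = character(0),
                                  sex = character(0), age = numeric(0)),
                       provenance = paste0("synthetic(seed=", cfg$seed, ")"))
    attr(empty, "latent_severity") <- numeric(0)
    return(empty)
  }
  set.seed(cfg$seed)
  mdl <- synthetic_component_model()

  male <- stats::rbinom(n, 1, cfg$sex_ratio_male)
  group <- sample.int(3, n, replace = TRUE, prob = cfg$age_weights)
  age <- stats::rnorm(n, cfg$age_means[group], cfg$age_sds[group])
  age <- pmin(pmax(age, cfg$age_range[1]), cfg$age_range[2])
  sev <- stats::rnorm(n)
  lip <- stats::rnorm(n)
  a <- age - 40

  draw <- function(p) {
    x <- p$mean + (p$age %||% 0) * a + (p$male %||% 0) * male +
      cfg$severity_scale * p$load * sev +
      cfg$lipid_axis_scale * (p$lipid %||% 0) * lip +
      stats::rnorm(n, 0, p$noise)
    if (!is.null(p$min)) x <- pmax(x, p$min)
    x
  }

  sbp <- pmax(draw(mdl$sbp), 85)
  gap <- pmax(stats::rnorm(n, mdl$dbp_gap$mean, mdl$dbp_gap$noise),
              mdl$dbp_gap$min)
  dbp <- sbp - gap
  tg <- exp(draw(mdl$log_tg))
  hdl <- draw(mdl$hdl)
  glucose <- draw(mdl$glucose)
  insulin <- exp(draw(mdl$log_insulin))
  height <- ifelse(male == 1,
                   stats::rnorm(n, mdl$height$male_mean, mdl$height$male_sd),
                   stats::rnorm(n, mdl$height$female_mean,
                                mdl$height$female_sd)) * growth_fraction(age)
  waist <- draw(mdl$whtr) * height
  weight <- draw(mdl$bmi) * (height / 100)^2
  fh <- stats::runif(n) < cfg$family_history_prevalence

  df <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    sex = ifelse(male == 1, "male", "female"),
    age = age, height = height, weight = weight, waist = waist,
    systolic_bp = sbp, diastolic_bp = dbp, glucose = glucose,
    insulin = insulin, triglycerides = tg, hdl = hdl,
    family_history_cv = fh,
    treated_lipids = FALSE, treated_bp = FALSE, treated_glucose = FALSE,
    treated_hdl = FALSE,
    stringsAsFactors = FALSE
  )
  for (field in names(cfg$missingness)) {
    rate <- cfg$missingness[[field]]
    if (rate > 0) {
      hit <- stats::runif(n) < rate
      df[[field]][hit] <- NA
    }
  }
  cohort <- as_cohort(df, provenance = paste0("synthetic(seed=", cfg$seed, ")"))
  attr(cohort, "latent_severity") <- sev
  cohort
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Ten worked example subjects (five patients, two visits each)
#'
#' A fixed fixture of five patients observed at baseline and follow-up, with
#' the component values used throughout the documentation and tests for
#' exact siMS and siMS risk score checks. Family history is a patient-level
#' trait and carries over to the follow-up visit.
#'
#' @return A `sims_cohort` of 10 fully scoreable subjects.
#' @examples
#' score_cohort(table2_fixture())
#' @export
table2_fixture <- function() {
  df <- data.frame(
    subject_id = c("p1_baseline", "p1_followup", "p2_baseline", "p2_followup",
                   "p3_baseline", "p3_followup", "p4_baseline", "p4_followup",
                   "p5_baseline", "p5_followup"),
    sex = c("f", "f", "m", "m", "f", "f", "f", "f", "m", "m"),
    waist = c(132, 120, 104, 103, 99, 93, 95, 90, 141, 131),
    height = c(167, 168, 190, 190, 161, 161, 161, 161, 180, 180),
    systolic_bp = c(120, 120, 140, 140, 130, 120, 160, 130, 125, 110),
    hdl = c(0.91, 1.45, 1.03, 1.10, 1.17, 1.30, 1.19, 1.20, 1.25, 1.20),
    triglycerides = c(2.49, 1.31, 2.09, 1.90, 2.88, 1.90, 1.80, 1.60,
                      1.58, 1.40),
    glucose = c(5.7, 5.2, 5.5, 5.4, 5.0, 5.3, 5.2, 5.0, 5.3, 5.4),
    age = c(20, 22, 30, 37, 53, 54, 42, 52, 36, 39),
    family_history_cv = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
                          FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  as_cohort(df, provenance = "table2_fixture")
}
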