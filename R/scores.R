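hdl_denominator <- function(sex, ref) {
  ifelse(sex == "male", ref$hdl_ref_male,
         ifelse(sex == "female", ref$hdl_ref_female, NA_real_))
}

age_reference <- function(sex, ref) {
  ifelse(sex == "male", ref$age_ref_male,
         ifelse(sex == "female", ref$age_ref_female, NA_real_))
}

#' siMS score: cutoff-normalized continuous metabolic syndrome severity
#'
#' Each metabolic syndrome component enters divided by its diagnostic cutoff,
#' abdominal obesity as twice the waist-to-height ratio, and HDL negatively:
#'
#' \deqn{2\,\frac{Waist}{Height} + \frac{Gly}{5.6} + \frac{Tg}{1.7} +
#'   \frac{SBP}{130} - \frac{HDL}{1.02\ (m)\ /\ 1.28\ (f)}}
#'
#' A subject sitting exactly at every cutoff with a waist-to-height ratio of
#' 0.5 scores exactly 3. All cutoffs come from `ref` and can be replaced by
#' population-specific values; with `ref$tg_double_ref` the triglyceride term
#' is divided by twice its cutoff. Results are full precision; use
#' [format_score()] for the conventional 2-decimal display.
#'
#' All arguments are vectorized; a missing value in any required input gives
#' a missing score for that subject (no imputation).
#'
#' @param waist Waist circumference, cm.
#' @param height Height, cm.
#' @param glucose Fasting glucose, mmol/L.
#' @param triglycerides Fasting triglycerides, mmol/L.
#' @param systolic_bp Systolic blood pressure, mmHg.
#' @param hdl HDL cholesterol, mmol/L.
#' @param sex `"male"` or `"female"` (selects the HDL denominator).
#' @param ref A [sims_reference()] configuration.
#' @return Numeric vector of siMS scores (dimensionless).
#' @examples
#' sims_score(waist = 132, height = 167, glucose = 5.7, triglycerides = 2.49,
#'            systolic_bp = 120, hdl = 0.91, sex = "female")
#' @export
sims_score <- function(waist, height, glucose, triglycerides, systolic_bp,
                       hdl, sex, ref = sims_reference()) {
  stopifnot(inherits(ref, "sims_reference"))
  tg_den <- if (ref$tg_double_ref) 2 * ref$tg_ref else ref$tg_ref
  2 * waist / height +
    glucose / ref$gly_ref +
    triglycerides / tg_den +
    systolic_bp / ref$sbp_ref -
    hdl / hdl_denominator(sex, ref)
}

#' siMS risk score: age- and heredity-adjusted siMS score
#'
#' Multiplies the (full-precision) siMS score by `age / age_ref` with a
#' sex-specific reference age (45 for men, 50 for women, near the ages where
#' cardio/cerebro-vascular incidence rises) and by a family-history
#' multiplier (1.2 when a positive family history of cardio- or
#' cerebro-vascular events is present, 1 otherwise).
#'
#' @param sims Numeric vector of siMS scores (unrounded).
#' @param age Age in years.
#' @param sex `"male"` or `"female"`.
#' @param family_history Logical: positive family history of
#'   cardio/cerebro-vascular events. `NA` gives a missing risk score; the
#'   score treats a recorded `FALSE` as a known negative, never as unknown.
#' @param ref A [sims_reference()] configuration.
#' @return Numeric vector of siMS risk scores.
#' @examples
#' s <- sims_score(132, 167, 5.7, 2.49, 120, 0.91, "female")
#' sims_risk_score(s, age = 20, sex = "female", family_history = TRUE)
#' @export
sims_risk_score <- function(sims, age, sex, family_history,
                            ref = sims_reference()) {
  stopifnot(inherits(ref, "sims_reference"))
  mult <- ifelse(family_history, ref$family_history_multiplier, 1)
  sims * age / age_reference(sex, ref) * mult
}

#' Derived clinical measures
#'
#' Standard quantities computed alongside the scores: body mass index,
#' mean arterial pressure (DBP + (SBP - DBP)/3), average arterial pressure
#' ((SBP + DBP)/2) and the HOMA-IR insulin resistance index
#' (fasting insulin in mIU/L times fasting glucose in mmol/L, divided
#' by 22.5). All are vectorized and propagate missing inputs.
#'
#' @param weight Weight, kg.
#' @param height Height, cm.
#' @param systolic_bp,diastolic_bp Blood pressures, mmHg.
#' @param insulin Fasting insulin, mIU/L (must be positive when present).
#' @param glucose Fasting glucose, mmol/L (must be positive when present).
#' @return Numeric vector (kg/m2, mmHg, mmHg, dimensionless respectively).
#' @examples
#' bmi(70, 175)
#' mean_arterial_pressure(120, 80)
#' average_arterial_pressure(120, 80)
#' homa_ir(22.5, 5)
#' @export
bmi <- function(weight, height) {
  weight / (height / 100)^2
}

#' @rdname bmi
#' @export
mean_arterial_pressure <- function(systolic_bp, diastolic_bp) {
  diastolic_bp + (systolic_bp - diastolic_bp) / 3
}

#' @rdname bmi
#' @export
average_arterial_pressure <- function(systolic_bp, diastolic_bp) {
  (systolic_bp + diastolic_bp) / 2
}

#' @rdname bmi
#' @export
homa_ir <- function(insulin, glucose) {
  if (any(insulin <= 0, na.rm = TRUE) || any(glucose <= 0, na.rm = TRUE)) {
    stop("homa_ir() requires strictly positive insulin and glucose.",
         call. = FALSE)
  }
  insulin * glucose / 22.5
}

#' Format a score for display
#'
#' Scores are kept at full precision internally; the conventional display is
#' two decimals with round-half-up (so 2.005 prints as "2.01", unlike R's
#' banker's rounding).
#'
#' @param x Numeric vector.
#' @param digits Decimal places. Default 2.
#' @return Character vector ("" for missing).
#' @export
format_score <- function(x, digits = 2) {
  out <- formatC(round_half_up(x, digits), format = "f", digits = digits)
  out[is.na(x)] <- ""
  out
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Score a cohort
#'
#' Computes siMS and siMS risk scores plus the derived measures for every
#' subject of a cohort, complete-case per quantity: a score is present
#' exactly when every input it needs is present. Row order is preserved and
#' the computation is deterministic.
#'
#' The risk score needs a recorded family history. With
#' `assume_no_family_history = TRUE` a missing `family_history_cv` is treated
#' as a known negative (multiplier 1); by default it stays missing, because
#' an unrecorded history is unknown, not absent.
#'
#' @param cohort A `sims_cohort` (see [as_cohort()]).
#' @param ref A [sims_reference()] configuration.
#' @param assume_no_family_history Logical, default `FALSE`.
#' @return A tibble with `subject_id`, `sims_score`, `sims_risk_score`,
#'   `bmi`, `map`, `avap`, `homa_ir`, with attribute `completeness` holding
#'   per-column complete-case counts.
#' @examples
#' tab <- score_cohort(table2_fixture())
#' head(tab)
#' attr(tab, "completeness")
#' @export
score_cohort <- function(cohort, ref = sims_reference(),
                         assume_no_family_history = FALSE) {
  stopifnot(inherits(cohort, "sims_cohort"))
  if (nrow(cohort) == 0) {
    warning("Empty cohort: returning an empty score table.", call. = FALSE)
  }
  fh <- cohort$family_history_cv
  if (assume_no_family_history) fh[is.na(fh)] <- FALSE
  sims <- sims_score(cohort$waist, cohort$height, cohort$glucose,
                     cohort$triglycerides, cohort$systolic_bp, cohort$hdl,
                     cohort$sex, ref)
  ins <- cohort$insulin
  gly <- cohort$glucose
  out <- tibble::tibble(
    subject_id = cohort$subject_id,
    sims_score = sims,
    sims_risk_score = sims_risk_score(sims, cohort$age, cohort$sex, fh, ref),
    bmi = bmi(cohort$weight, cohort$height),
    map = mean_arterial_pressure(cohort$systolic_bp, cohort$diastolic_bp),
    avap = average_arterial_pressure(cohort$systolic_bp, cohort$diastolic_bp),
    homa_ir = ifelse(is.na(ins) | is.na(gly), NA_real_, ins * gly / 22.5)
  )
  attr(out, "completeness") <- column_completeness(out[-1])
  out
}
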