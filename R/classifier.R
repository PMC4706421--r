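# Three-valued helpers: flags are TRUE/FALSE/NA and a TRUE treatment flag
# dominates (a treated component counts as fulfilled whatever its value).
flag_or_treat <- function(measured_flag, treated) {
  treated_true <- !is.na(treated) & treated
  ifelse(treated_true, TRUE, measured_flag)
}

# >= 3 of 5 with explicit ambiguity: TRUE once three criteria are certainly
# met, FALSE once three can no longer be reached, NA otherwise.
ms_from_flags <- function(flag_matrix, threshold = 3) {
  n_true <- rowSums(flag_matrix, na.rm = TRUE)
  n_na <- rowSums(is.na(flag_matrix))
  ifelse(n_true >= threshold, TRUE,
         ifelse(n_true + n_na < threshold, FALSE, NA))
}

adult_flags <- function(cohort, ref) {
  waist_cut <- ifelse(cohort$sex == "male", ref$waist_male,
                      ifelse(cohort$sex == "female", ref$waist_female,
                             NA_real_))
  hdl_cut <- ifelse(cohort$sex == "male", ref$hdl_class_male,
                    ifelse(cohort$sex == "female", ref$hdl_class_female,
                           NA_real_))
  tibble::tibble(
    waist_flag = cohort$waist >= waist_cut,
    tg_flag = flag_or_treat(cohort$triglycerides >= ref$tg_ref,
                            cohort$treated_lipids),
    hdl_flag = flag_or_treat(cohort$hdl < hdl_cut, cohort$treated_hdl),
    bp_flag = flag_or_treat(
      (cohort$systolic_bp >= ref$sbp_ref) | (cohort$diastolic_bp >= ref$dbp_ref),
      cohort$treated_bp),
    glucose_flag = flag_or_treat(cohort$glucose >= ref$gly_ref,
                                 cohort$treated_glucose)
  )
}

pediatric_waist_flag <- function(cohort, ped) {
  if (is.null(ped$waist_p90)) return(rep(NA, nrow(cohort)))
  tab <- ped$waist_p90
  band <- pmin(pmax(floor(cohort$age), min(tab$age)), max(tab$age))
  idx <- match(band, tab$age)
  cut <- ifelse(cohort$sex == "male", tab$male[idx],
                ifelse(cohort$sex == "female", tab$female[idx], NA_real_))
  cohort$waist >= cut
}

pediatric_flags <- function(cohort, ped) {
  tibble::tibble(
    waist_flag = pediatric_waist_flag(cohort, ped),
    tg_flag = flag_or_treat(cohort$triglycerides >= ped$tg_cutoff,
                            cohort$treated_lipids),
    hdl_flag = flag_or_treat(cohort$hdl < ped$hdl_cutoff, cohort$treated_hdl),
    bp_flag = flag_or_treat(
      (cohort$systolic_bp >= ped$sbp_cutoff) |
        (cohort$diastolic_bp >= ped$dbp_cutoff),
      cohort$treated_bp),
    glucose_flag = flag_or_treat(cohort$glucose >= ped$gly_cutoff,
                                 cohort$treated_glucose)
  )
}

# IDF-style pediatric decision for 10 to <16: abdominal obesity is mandatory,
# plus at least two of the remaining four criteria.
ms_pediatric_rule <- function(flags) {
  others <- as.matrix(flags[c("tg_flag", "hdl_flag", "bp_flag",
                              "glucose_flag")])
  o_true <- rowSums(others, na.rm = TRUE)
  o_na <- rowSums(is.na(others))
  waist <- flags$waist_flag
  ifelse(!is.na(waist) & !waist, FALSE,
         ifelse(o_true + o_na < 2, FALSE,
                ifelse(!is.na(waist) & waist & o_true >= 2, TRUE, NA)))
}

flag_names <- c("waist_flag", "tg_flag", "hdl_flag", "bp_flag",
                "glucose_flag")

count_components <- function(flags) {
  m <- as.matrix(flags[flag_names])
  ifelse(rowSums(is.na(m)) > 0, NA_integer_, as.integer(rowSums(m)))
}

#' Classify metabolic syndrome in adults
#'
#' Applies the 2009 joint harmonized definition: metabolic syndrome is
#' present with at least 3 of 5 criteria — waist circumference >= 94 cm
#' (men) / 80 cm (women), triglycerides >= 1.7 mmol/L, HDL < 1.03 (men) /
#' 1.29 (women) mmol/L, blood pressure systolic >= 130 and/or diastolic
#' >= 85 mmHg, fasting glucose >= 5.6 mmol/L. Drug treatment for lipids,
#' blood pressure, glucose or HDL makes the corresponding criterion
#' fulfilled regardless of the measured value.
#'
#' A component with neither measurement nor treatment flag is missing, and
#' `ms_present` is missing whenever the missing flags leave the >= 3 decision
#' ambiguous (never imputed, since the classification serves as ROC ground
#' truth downstream). `n_components` is reported only when all five flags
#' are known.
#'
#' @param cohort A `sims_cohort`.
#' @param ref A [sims_reference()] (supplies all cutoffs).
#' @return Tibble: `subject_id`, the five component flags, `n_components`
#'   (0-5), `ms_present`.
#' @export
classify_adult <- function(cohort, ref = sims_reference()) {
  stopifnot(inherits(cohort, "sims_cohort"))
  flags <- adult_flags(cohort, ref)
  flags$ms_present <- ms_from_flags(as.matrix(flags[flag_names]))
  flags$n_components <- count_components(flags)
  tibble::tibble(subject_id = cohort$subject_id,
                 flags[c(flag_names, "n_components", "ms_present")])
}

#' Classify metabolic syndrome in children and adolescents
#'
#' IDF-consensus structure: below `ped$min_age` (default 10) the syndrome is
#' not defined and everything is missing; from 10 to under 16 abdominal
#' obesity (waist at or above the configured 90th percentile for age and
#' sex) is mandatory plus at least two of elevated triglycerides, reduced
#' HDL, raised blood pressure or raised glucose; from `ped$adult_age`
#' (default 16) the adult rule of [classify_adult()] applies. Treatment
#' flags dominate as in adults.
#'
#' @param cohort A `sims_cohort`; subjects should be under 18.
#' @param ped A [pediatric_reference()] configuration (waist percentiles are
#'   population-specific; the shipped default table is synthetic).
#' @param ref A [sims_reference()] for the >= 16 handover.
#' @return Tibble as in [classify_adult()].
#' @export
classify_pediatric <- function(cohort, ped = pediatric_reference(),
                               ref = sims_reference()) {
  stopifnot(inherits(cohort, "sims_cohort"), inherits(ped, "sims_pediatric"))
  n <- nrow(cohort)
  out <- tibble::tibble(
    subject_id = cohort$subject_id,
    waist_flag = rep(NA, n), tg_flag = rep(NA, n), hdl_flag = rep(NA, n),
    bp_flag = rep(NA, n), glucose_flag = rep(NA, n),
    n_components = rep(NA_integer_, n), ms_present = rep(NA, n)
  )
  age <- cohort$age
  too_young <- !is.na(age) & age < ped$min_age
  if (any(too_young)) {
    warning(sum(too_young), " subject(s) below ", ped$min_age,
            " years: metabolic syndrome classification is not defined.",
            call. = FALSE)
  }
  adultish <- !is.na(age) & age >= ped$adult_age
  if (any(adultish)) {
    out[adultish, -1] <- classify_adult(cohort[adultish, ], ref)[-1]
  }
  band <- !is.na(age) & age >= ped$min_age & age < ped$adult_age
  if (any(band)) {
    flags <- pediatric_flags(cohort[band, ], ped)
    flags$ms_present <- ms_pediatric_rule(flags)
    flags$n_components <- count_components(flags)
    out[band, -1] <- flags[c(flag_names, "n_components", "ms_present")]
  }
  out
}

#' Age-dispatching metabolic syndrome classification
#'
#' Adults (age >= 18) go through [classify_adult()]; younger subjects
#' through [classify_pediatric()] (which itself hands 16-17-year-olds to the
#' adult rule and leaves under-10s unclassified). Subjects with missing age
#' are unclassifiable.
#'
#' @inheritParams classify_pediatric
#' @return Tibble as in [classify_adult()], row order preserved.
#' @examples
#' cls <- classify_ms(table2_fixture())
#' table(cls$ms_present)
#' @export
classify_ms <- function(cohort, ref = sims_reference(),
                        ped = pediatric_reference()) {
  stopifnot(inherits(cohort, "sims_cohort"))
  n <- nrow(cohort)
  out <- tibble::tibble(
    subject_id = cohort$subject_id,
    waist_flag = rep(NA, n), tg_flag = rep(NA, n), hdl_flag = rep(NA, n),
    bp_flag = rep(NA, n), glucose_flag = rep(NA, n),
    n_components = rep(NA_integer_, n), ms_present = rep(NA, n)
  )
  age <- cohort$age
  adult <- !is.na(age) & age >= 18
  child <- !is.na(age) & age < 18
  if (any(adult)) out[adult, -1] <- classify_adult(cohort[adult, ], ref)[-1]
  if (any(child)) {
    out[child, -1] <- classify_pediatric(cohort[child, ], ped, ref)[-1]
  }
  out
}

#' Metabolic syndrome component count
#'
#' Number of fulfilled criteria (0-5) from the age-appropriate classifier;
#' missing when any component flag is missing. Used as a crude comparator
#' for continuous scores.
#'
#' @inheritParams classify_ms
#' @return Integer vector aligned with the cohort rows.
#' @export
component_count <- function(cohort, ref = sims_reference(),
                            ped = pediatric_reference()) {
  classify_ms(cohort, ref, ped)$n_components
}
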