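#' Reference configuration for siMS scoring and MS classification
#'
#' Bundles every cutoff and multiplier that parameterizes the siMS score, the
#' siMS risk score and the dichotomous metabolic syndrome classifier. The
#' defaults are the harmonized 2009 joint-definition cutoffs; any of them can
#' be replaced with laboratory-, nation- or population-specific values without
#' touching the scoring code.
#'
#' The score denominators for HDL (1.02 male / 1.28 female) deliberately
#' differ from the classifier cutoffs (1.03 / 1.29): the continuous formula is
#' conventionally written with the former, while the dichotomous definition
#' uses the latter. Both are exposed so either convention can be overridden.
#'
#' @param gly_ref Fasting glucose denominator, mmol/L. Default 5.6.
#' @param tg_ref Triglyceride denominator, mmol/L. Default 1.7.
#' @param sbp_ref Systolic blood pressure denominator, mmHg. Default 130.
#' @param hdl_ref_male,hdl_ref_female HDL score denominators, mmol/L.
#'   Defaults 1.02 and 1.28.
#' @param age_ref_male,age_ref_female Reference ages (years) for the risk
#'   score, chosen as the ages where cardio/cerebro-vascular incidence rises
#'   (menopause for women). Defaults 45 and 50.
#' @param family_history_multiplier Risk multiplier applied when a positive
#'   family history of cardio/cerebro-vascular events is present. Default 1.2
#'   (a 20\% excess risk); must be >= 1.
#' @param tg_double_ref Logical; if \code{TRUE} the triglyceride term is
#'   divided by \code{2 * tg_ref} instead of \code{tg_ref}. Off by default:
#'   the single-reference form is the canonical score.
#' @param waist_male,waist_female Classifier waist-circumference cutoffs, cm
#'   (>= flags abdominal obesity). Defaults 94 and 80.
#' @param hdl_class_male,hdl_class_female Classifier HDL cutoffs, mmol/L
#'   (strictly below flags reduced HDL). Defaults 1.03 and 1.29.
#' @param dbp_ref Classifier diastolic pressure cutoff, mmHg. Default 85.
#'
#' @return An object of class \code{sims_reference}: a named list of the
#'   validated cutoffs.
#' @examples
#' ref <- sims_reference()
#' ref$gly_ref
#' # population-specific waist cutoffs:
#' sims_reference(waist_male = 90, waist_female = 80)
#' @export
sims_reference <- function(gly_ref = 5.6,
                           tg_ref = 1.7,
                           sbp_ref = 130,
                           hdl_ref_male = 1.02,
                           hdl_ref_female = 1.28,
                           age_ref_male = 45,
                           age_ref_female = 50,
                           family_history_multiplier = 1.2,
                           tg_double_ref = FALSE,
                           waist_male = 94,
                           waist_female = 80,
                           hdl_class_male = 1.03,
                           hdl_class_female = 1.29,
                           dbp_ref = 85) {
  ref <- list(
    gly_ref = gly_ref, tg_ref = tg_ref, sbp_ref = sbp_ref,
    hdl_ref_male = hdl_ref_male, hdl_ref_female = hdl_ref_female,
    age_ref_male = age_ref_male, age_ref_female = age_ref_female,
    family_history_multiplier = family_history_multiplier,
    tg_double_ref = isTRUE(tg_double_ref),
    waist_male = waist_male, waist_female = waist_female,
    hdl_class_male = hdl_class_male, hdl_class_female = hdl_class_female,
    dbp_ref = dbp_ref
  )
  numeric_fields <- setdiff(names(ref), "tg_double_ref")
  for (f in numeric_fields) {
    v <- ref[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("Reference field '", f, "' must be a single positive number.",
           call. = FALSE)
    }
  }
  if (ref$family_history_multiplier < 1) {
    stop("family_history_multiplier must be >= 1.", call. = FALSE)
  }
  structure(ref, class = "sims_reference")
}

#' @export
print.sims_reference <- function(x, ...) {
  cat("siMS reference configuration\n")
  cat(sprintf("  score denominators: Gly %.3g, Tg %.3g%s, SBP %.3g, HDL %.3g (m) / %.3g (f)\n",
              x$gly_ref, x$tg_ref,
              if (x$tg_double_ref) " (doubled)" else "",
              x$sbp_ref, x$hdl_ref_male, x$hdl_ref_female))
  cat(sprintf("  risk score: age ref %.3g (m) / %.3g (f), family-history x%.3g\n",
              x$age_ref_male, x$age_ref_female, x$family_history_multiplier))
  cat(sprintf("  classifier: waist >= %.3g/%.3g, HDL < %.3g/%.3g, BP >= %.3g/%.3g, Gly >= %.3g\n",
              x$waist_male, x$waist_female, x$hdl_class_male,
              x$hdl_class_female, x$sbp_ref, x$dbp_ref, x$gly_ref))
  invisible(x)
}

#' Read or write a reference configuration as JSON
#'
#' The JSON form carries exactly the fields of [sims_reference()]; absent
#' fields fall back to the defaults, so a config file only needs to name the
#' cutoffs it overrides.
#'
#' @param path File path.
#' @param ref A `sims_reference` object (for writing).
#' @return `read_reference()` returns a `sims_reference`;
#'   `write_reference()` returns `path` invisibly.
#' @export
read_reference <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sims_reference))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warning("Ignoring unknown reference fields: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(sims_reference, raw)
}

#' @rdname read_reference
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "sims_reference"))
  jsonlite::write_json(unclass(ref), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Pediatric classification configuration
#'
#' Age-banded cutoffs for the pediatric metabolic syndrome classifier,
#' following the IDF consensus structure: below 10 years the syndrome is not
#' defined; from 10 to under 16 abdominal obesity (waist at or above the
#' population 90th percentile) is mandatory plus at least two of the other
#' four components, with fixed cutoffs for triglycerides, HDL, blood pressure
#' and glucose; from 16 on the adult rule applies.
#'
#' The consensus definition relies on population-specific waist percentiles
#' that no single table can supply universally. The default `waist_p90`
#' table shipped here is a synthetic linear approximation of school-age
#' waist-percentile growth (see the package vignette) intended for testing
#' and simulation; replace it with the percentile table for your population
#' for clinical use.
#'
#' @param min_age Years below which classification is undefined. Default 10.
#' @param adult_age Years at and above which the adult rule applies within
#'   the pediatric path. Default 16.
#' @param tg_cutoff,hdl_cutoff,sbp_cutoff,dbp_cutoff,gly_cutoff Fixed
#'   component cutoffs for the 10 to <16 band (Tg >= 1.7 mmol/L,
#'   HDL < 1.03 mmol/L, SBP >= 130 or DBP >= 85 mmHg, glucose >= 5.6 mmol/L).
#' @param waist_p90 Data frame with columns `age` (integer years), `male`
#'   and `female` (waist 90th percentile, cm). Lookup uses the row whose age
#'   equals `floor(age)`, clamped to the table range. `NULL` disables the
#'   waist component (its flag becomes missing).
#' @return An object of class `sims_pediatric`.
#' @export
pediatric_reference <- function(min_age = 10,
                                adult_age = 16,
                                tg_cutoff = 1.7,
                                hdl_cutoff = 1.03,
                                sbp_cutoff = 130,
                                dbp_cutoff = 85,
                                gly_cutoff = 5.6,
                                waist_p90 = default_waist_p90()) {
  if (!is.null(waist_p90)) {
    waist_p90 <- as.data.frame(waist_p90)
    need <- c("age", "male", "female")
    if (!all(need %in% names(waist_p90))) {
      stop("waist_p90 must have columns age, male, female.", call. = FALSE)
    }
  }
  structure(list(
    min_age = min_age, adult_age = adult_age,
    tg_cutoff = tg_cutoff, hdl_cutoff = hdl_cutoff,
    sbp_cutoff = sbp_cutoff, dbp_cutoff = dbp_cutoff,
    gly_cutoff = gly_cutoff, waist_p90 = waist_p90
  ), class = "sims_pediatric")
}

#' Synthetic default waist 90th-percentile table for ages 10-15
#'
#' A linear approximation of waist-circumference 90th percentiles across
#' school ages, shipped so the pediatric classifier is runnable out of the
#' box on simulated cohorts. These are synthetic package defaults, not
#' measured population percentiles.
#'
#' @return Data frame with columns `age`, `male`, `female` (cm).
#' @export
default_waist_p90 <- function() {
  age <- 10:15
  data.frame(
    age = age,
    male = 72 + 2.8 * (age - 10),
    female = 70 + 2.5 * (age - 10)
  )
}
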