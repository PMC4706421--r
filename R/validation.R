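#' Pearson correlation with optional log transforms
#'
#' Product-moment correlation on pairwise complete cases, with optional
#' natural-log transforms of either vector (the usual normalization for
#' right-skewed clinical variables); two-sided p-value from the t
#' distribution with n - 2 degrees of freedom, via [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length.
#' @param log_x,log_y Apply `log()` before correlating; every retained value
#'   must be positive.
#' @return List of class `correlation_result`: `r`, `n`, `p_value`,
#'   `log_x`, `log_y`.
#' @examples
#' pearson_cor(1:10, 2 * (1:10) + 1)$r
#' @export
pearson_cor <- function(x, y, log_x = FALSE, log_y = FALSE) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (log_x) {
    bad <- which(x <= 0)
    if (length(bad) > 0) {
      stop("log_x requires positive values; offending index ", bad[1],
           " (value ", x[bad[1]], ").", call. = FALSE)
    }
    x <- log(x)
  }
  if (log_y) {
    bad <- which(y <= 0)
    if (length(bad) > 0) {
      stop("log_y requires positive values; offending index ", bad[1],
           " (value ", y[bad[1]], ").", call. = FALSE)
    }
    y <- log(y)
  }
  if (length(x) < 3) {
    stop("Pearson correlation needs at least 3 complete pairs.",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson correlation undefined: zero variance.", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), n = length(x),
                 p_value = ct$p.value, log_x = log_x, log_y = log_y),
            class = "correlation_result")
}

#' Correlation table of a primary score against comparators
#'
#' One row per comparator column: Pearson r, n (pairwise complete cases) and
#' p-value of the primary score against each comparator, mirroring the
#' conventional presentation of continuous metabolic syndrome score
#' validation (whole-sample and age-stratified variants side by side when
#' both are passed in).
#'
#' @param score_table Data frame of per-subject scores.
#' @param primary Name of the primary score column.
#' @param comparators Character vector of comparator column names.
#' @param log_primary,log_comparators Optional log transforms (scalar or one
#'   per comparator for `log_comparators`).
#' @return Tibble: `comparator`, `r`, `n`, `p_value`. A comparator with no
#'   usable overlap yields an `NA` row with a warning.
#' @export
correlation_table <- function(score_table, primary, comparators,
                              log_primary = FALSE, log_comparators = FALSE) {
  stopifnot(primary %in% names(score_table),
            all(comparators %in% names(score_table)))
  log_comparators <- rep_len(log_comparators, length(comparators))
  rows <- lapply(seq_along(comparators), function(i) {
    res <- tryCatch(
      pearson_cor(score_table[[primary]], score_table[[comparators[i]]],
                  log_x = log_primary, log_y = log_comparators[i]),
      error = function(e) {
        warning("Correlation with '", comparators[i], "' unavailable: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(res)) {
      tibble::tibble(comparator = comparators[i], r = NA_real_,
                     n = NA_integer_, p_value = NA_real_)
    } else {
      tibble::tibble(comparator = comparators[i], r = res$r, n = res$n,
                     p_value = res$p_value)
    }
  })
  dplyr::bind_rows(rows)
}

#' ROC area under the curve against a dichotomous state
#'
#' AUC by the Mann-Whitney construction with midrank tie handling,
#' \eqn{AUC = U / (n_+ n_-)}: the probability that a random positive scores
#' higher than a random negative, ties counting one half. Orientation is
#' fixed — higher score predicts the positive label — and never auto-flipped,
#' so an anti-discriminating score honestly reports AUC < 0.5. The 95\% CI
#' uses the Hanley-McNeil standard-error formula with a normal
#' approximation, truncated to [0, 1]; the method is recorded in the result.
#'
#' @param scores Numeric vector (finite where labels are present).
#' @param labels Logical (or 0/1) vector: `TRUE` = state present. Pairs with
#'   a missing score or label are dropped.
#' @return List of class `roc_result`: `auc`, `ci95_low`, `ci95_high`,
#'   `n_pos`, `n_neg`, `se`, `ci_method`.
#' @examples
#' roc_auc(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE))$auc
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_auc needs both classes present (", n_pos, " positive, ",
         n_neg, " negative).", call. = FALSE)
  }
  if (any(!is.finite(scores))) {
    stop("roc_auc requires finite scores.", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  if (stats::sd(scores) == 0) {
    warning("All scores tied: AUC is 0.5 with a degenerate CI.",
            call. = FALSE)
    return(structure(list(auc = 0.5, ci95_low = 0, ci95_high = 1,
                          n_pos = n_pos, n_neg = n_neg, se = NA_real_,
                          ci_method = "degenerate"),
                     class = "roc_result"))
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(0.975)
  structure(list(auc = auc,
                 ci95_low = max(0, auc - z * se),
                 ci95_high = min(1, auc + z * se),
                 n_pos = n_pos, n_neg = n_neg, se = se,
                 ci_method = "hanley_mcneil_normal"),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f; %d positive, %d negative)\n",
              x$auc, x$ci95_low, x$ci95_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, p = %.3g)%s%s\n", x$r, x$n,
              x$p_value,
              if (x$log_x) ", log(x)" else "",
              if (x$log_y) ", log(y)" else ""))
  invisible(x)
}

#' Full validation report for a cohort
#'
#' Runs the whole evaluation pipeline on one cohort: scores it, computes
#' the requested comparator scores, the correlation table of the siMS score
#' against every comparator (plus the component count), and ROC/AUC of the
#' siMS, z-sum and PCA weighted-sum scores against the dichotomous
#' metabolic syndrome classification. A comparator whose computation fails
#' (degenerate data) is reported as failed; all other cells are still
#' computed. An externally computed risk comparator (for instance a
#' published 10-year cardiovascular risk score) can be supplied as a
#' per-subject column and is correlated, log-transformed, with the siMS
#' risk score.
#'
#' @param cohort A `sims_cohort`.
#' @param ref A [sims_reference()].
#' @param ped A [pediatric_reference()].
#' @param specs List of [comparator_spec()]s; the default covers the seven
#'   conventional whole-sample comparators (component count, three z-sum
#'   variants, four PCA variants minus the insulin ones).
#' @param external_risk Optional numeric vector, one value per cohort row:
#'   an externally computed risk score to correlate (log-transformed) with
#'   the siMS risk score.
#' @param assume_no_family_history Passed to [score_cohort()].
#' @return List of class `sims_validation`: `score_table` (scores,
#'   comparators and classification merged), `correlations`,
#'   `roc` (tibble of AUCs), `comparator_failures`, `completeness`.
#' @export
validate_cohort <- function(cohort, ref = sims_reference(),
                            ped = pediatric_reference(),
                            specs = default_comparator_specs(),
                            external_risk = NULL,
                            assume_no_family_history = FALSE) {
  stopifnot(inherits(cohort, "sims_cohort"))
  tab <- score_cohort(cohort, ref,
                      assume_no_family_history = assume_no_family_history)
  cls <- classify_ms(cohort, ref, ped)
  tab$n_components <- cls$n_components
  tab$ms_present <- cls$ms_present

  failures <- character(0)
  for (spec in specs) {
    res <- tryCatch(compute_comparator(cohort, spec), error = function(e) {
      warning("Comparator '", spec$label, "' failed: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) {
      failures <- c(failures, spec$label)
    } else {
      tab[[spec$label]] <- res$scores$score
    }
  }

  comp_cols <- c("n_components", vapply(specs, `[[`, "", "label"))
  comp_cols <- setdiff(comp_cols, failures)
  correlations <- correlation_table(tab, "sims_score", comp_cols)

  roc_cols <- intersect(c("sims_score", "z_sum_glucose",
                          "pca_weighted_sum_glucose"), names(tab))
  roc_rows <- lapply(roc_cols, function(col) {
    res <- tryCatch(roc_auc(tab[[col]], tab$ms_present),
                    error = function(e) NULL)
    if (is.null(res)) {
      tibble::tibble(score = col, auc = NA_real_, ci95_low = NA_real_,
                     ci95_high = NA_real_, n_pos = NA_integer_,
                     n_neg = NA_integer_)
    } else {
      tibble::tibble(score = col, auc = res$auc, ci95_low = res$ci95_low,
                     ci95_high = res$ci95_high, n_pos = res$n_pos,
                     n_neg = res$n_neg)
    }
  })
  roc <- dplyr::bind_rows(roc_rows)

  risk_vs_external <- NULL
  if (!is.null(external_risk)) {
    stopifnot(length(external_risk) == nrow(cohort))
    risk_vs_external <- tryCatch(
      pearson_cor(tab$sims_risk_score, external_risk, log_y = TRUE),
      error = function(e) NULL)
  }

  structure(list(score_table = tab, correlations = correlations, roc = roc,
                 comparator_failures = failures,
                 risk_vs_external = risk_vs_external,
                 completeness = column_completeness(tab)),
            class = "sims_validation")
}

#' Default whole-sample comparator set
#'
#' Component count aside (it is always included by [validate_cohort()]),
#' the conventional seven: z-sum with glucose, insulin and HOMA-IR, and the
#' four PCA variants (first component and weighted sum, each with glucose
#' and HOMA-IR).
#'
#' @param strata Optional age breakpoints applied to every spec.
#' @return List of [comparator_spec()]s.
#' @export
default_comparator_specs <- function(strata = NULL) {
  list(
    comparator_spec("z_sum", "glucose", strata = strata),
    comparator_spec("z_sum", "insulin", strata = strata),
    comparator_spec("z_sum", "homa", strata = strata),
    comparator_spec("pca_first_component", "glucose", strata = strata),
    comparator_spec("pca_weighted_sum", "glucose", strata = strata),
    comparator_spec("pca_first_component", "homa", strata = strata),
    comparator_spec("pca_weighted_sum", "homa", strata = strata)
  )
}

#' @export
print.sims_validation <- function(x, ...) {
  cat("Cohort validation report (", nrow(x$score_table), " subjects)\n",
      sep = "")
  cat("\nCorrelations with siMS score:\n")
  print(as.data.frame(x$correlations), row.names = FALSE, digits = 3)
  cat("\nROC against dichotomous metabolic syndrome:\n")
  print(as.data.frame(x$roc), row.names = FALSE, digits = 3)
  if (length(x$comparator_failures) > 0) {
    cat("\nFailed comparators:",
        paste(x$comparator_failures, collapse = ", "), "\n")
  }
  if (!is.null(x$risk_vs_external)) {
    cat("\nsiMS risk score vs log external risk score:\n")
    print(x$risk_vs_external)
  }
  invisible(x)
}
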