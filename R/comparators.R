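#' Specify a sample-derived comparator score
#'
#' The classical continuous metabolic syndrome scores are sample-specific:
#' sums of standardized residuals ("z-sum") and principal-component factor
#' scores. A `comparator_spec` pins down one variant: the method, which
#' glycemic variable stands in for glucoregulation (fasting glucose, fasting
#' insulin or HOMA-IR), which blood-pressure variable enters, and whether
#' the whole computation is repeated independently within age strata.
#'
#' Defaults follow the conventional component sets: z-sum uses systolic
#' pressure, PCA uses mean arterial pressure; triglycerides are always
#' log-transformed, insulin and HOMA-IR likewise (right-skewed variables).
#'
#' @param method `"z_sum"`, `"pca_first_component"` or `"pca_weighted_sum"`.
#' @param glycemic `"glucose"`, `"insulin"` or `"homa"`.
#' @param bp `"systolic"` or `"mean_arterial"`; default depends on method.
#' @param strata `NULL` for the whole sample, or a numeric vector of age
#'   breakpoints; `c(18, 31)` gives the conventional <18, 18-30, 31+ bands
#'   (see [age_strata_default()]).
#' @return A `comparator_spec` object with a deterministic `label`.
#' @examples
#' comparator_spec("z_sum", "glucose")
#' comparator_spec("pca_weighted_sum", "homa", strata = age_strata_default())
#' @export
comparator_spec <- function(method = c("z_sum", "pca_first_component",
                                       "pca_weighted_sum"),
                            glycemic = c("glucose", "insulin", "homa"),
                            bp = NULL,
                            strata = NULL) {
  method <- match.arg(method)
  glycemic <- match.arg(glycemic)
  if (is.null(bp)) bp <- if (method == "z_sum") "systolic" else "mean_arterial"
  bp <- match.arg(bp, c("systolic", "mean_arterial"))
  if (!is.null(strata)) {
    stopifnot(is.numeric(strata), !is.unsorted(strata), all(strata > 0))
  }
  label <- paste0(method, "_", glycemic,
                  if (bp != if (method == "z_sum") "systolic" else "mean_arterial")
                    paste0("_", bp) else "",
                  if (!is.null(strata)) "_stratified" else "")
  structure(list(method = method, glycemic = glycemic, bp = bp,
                 strata = strata, label = label),
            class = "comparator_spec")
}

#' Conventional age strata breakpoints
#'
#' Children (<18), young adults (18-30) and adults (31+).
#' @return Numeric vector `c(18, 31)`.
#' @export
age_strata_default <- function() c(18, 31)

stratum_index <- function(age, strata) {
  if (is.null(strata)) {
    out <- rep(1L, length(age))
    out[is.na(age)] <- NA_integer_
    return(out)
  }
  findInterval(age, strata) + 1L
}

stratum_labels <- function(strata) {
  if (is.null(strata)) return("all")
  lo <- c(-Inf, strata)
  hi <- c(strata, Inf)
  sprintf("[%s,%s)", ifelse(is.finite(lo), lo, "0"),
          ifelse(is.finite(hi), hi, "Inf"))
}

# Assemble the five component columns on their modelling scale, plus the
# covariates the spec'd method needs. Rows with any missing requirement are
# excluded (complete-case per variant).
comparator_matrix <- function(cohort, spec) {
  gly <- switch(spec$glycemic,
    glucose = cohort$glucose,
    insulin = log(cohort$insulin),
    homa = log(homa_ir_safe(cohort$insulin, cohort$glucose))
  )
  bp <- switch(spec$bp,
    systolic = cohort$systolic_bp,
    mean_arterial = mean_arterial_pressure(cohort$systolic_bp,
                                           cohort$diastolic_bp)
  )
  m <- cbind(waist = cohort$waist,
             bp = bp,
             log_tg = log(cohort$triglycerides),
             hdl = cohort$hdl,
             glycemic = gly)
  m
}

homa_ir_safe <- function(insulin, glucose) {
  ifelse(is.na(insulin) | is.na(glucose) | insulin <= 0 | glucose <= 0,
         NA_real_, insulin * glucose / 22.5)
}

#' Sum-of-z-scores comparator
#'
#' For each of the five components (waist circumference, blood pressure,
#' log triglycerides, HDL, glycemic variable) the component is regressed by
#' ordinary least squares on age (continuous) and sex (indicator, male = 1);
#' the residuals are standardized to mean 0, sd 1 (sample sd); the HDL
#' z-score is sign-flipped so that higher always means worse; the score is
#' the sum of the five z-scores. With age strata the whole procedure runs
#' independently within each stratum, making the score sample- and
#' stratum-specific by construction.
#'
#' If age and sex are both constant within a stratum the regression
#' degenerates to centering (with a warning); a component with zero residual
#' variance is an error naming the component.
#'
#' @param cohort A `sims_cohort`.
#' @param spec A [comparator_spec()] with `method = "z_sum"`.
#' @return A `comparator_result`: list with `scores` (tibble `subject_id`,
#'   `score`, `stratum`, aligned to the cohort and `NA` for incomplete
#'   cases), `label`, and per-stratum `diagnostics` (regression coefficients,
#'   residual sds, n).
#' @export
z_sum_score <- function(cohort, spec = comparator_spec("z_sum", "glucose")) {
  stopifnot(inherits(cohort, "sims_cohort"),
            inherits(spec, "comparator_spec"), spec$method == "z_sum")
  m <- comparator_matrix(cohort, spec)
  complete <- stats::complete.cases(m) & !is.na(cohort$age) &
    !is.na(cohort$sex)
  strat <- stratum_index(cohort$age, spec$strata)
  labels <- stratum_labels(spec$strata)
  score <- rep(NA_real_, nrow(cohort))
  stratum_col <- rep(NA_character_, nrow(cohort))
  diagnostics <- list()

  for (k in seq_along(labels)) {
    idx <- which(complete & !is.na(strat) & strat == k)
    if (length(idx) == 0) next
    if (length(idx) < 2) {
      stop("z_sum_score needs at least 2 complete cases per stratum (",
           labels[k], " has ", length(idx), ").", call. = FALSE)
    }
    age <- cohort$age[idx]
    male <- as.numeric(cohort$sex[idx] == "male")
    degenerate <- length(unique(age)) == 1 && length(unique(male)) == 1
    if (degenerate) {
      warning("Stratum ", labels[k], ": age and sex are constant; ",
              "z-scores fall back to centering only.", call. = FALSE)
    }
    z <- matrix(NA_real_, length(idx), ncol(m))
    coefs <- list()
    for (j in seq_len(ncol(m))) {
      y <- m[idx, j]
      if (degenerate) {
        res <- y - mean(y)
        coefs[[colnames(m)[j]]] <- c(`(Intercept)` = mean(y))
      } else {
        fit <- stats::lm(y ~ age + male)
        res <- stats::residuals(fit)
        coefs[[colnames(m)[j]]] <- stats::coef(fit)
      }
      s <- stats::sd(res)
      # residuals of a constant come back as ~1e-16 noise, not exact zeros
      if (!is.finite(s) || s < 1e-10 * max(1, abs(mean(m[idx, j])))) {
        stop("Component '", colnames(m)[j], "' has zero residual variance in ",
             "stratum ", labels[k], ".", call. = FALSE)
      }
      z[, j] <- (res - mean(res)) / s
    }
    z[, colnames(m) == "hdl"] <- -z[, colnames(m) == "hdl"]
    score[idx] <- rowSums(z)
    stratum_col[idx] <- labels[k]
    diagnostics[[labels[k]]] <- list(n = length(idx), coefficients = coefs)
  }

  structure(list(
    scores = tibble::tibble(subject_id = cohort$subject_id, score = score,
                            stratum = stratum_col),
    label = spec$label, spec = spec, diagnostics = diagnostics
  ), class = "comparator_result")
}

# Orient an eigenvector so its waist loading is non-negative; fall back to
# the log-Tg loading when the waist loading is exactly zero. Makes repeated
# runs bit-identical.
orient_component <- function(v) {
  pivot <- if (v[1] != 0) v[1] else v[3]
  if (pivot < 0) -v else v
}

#' Principal-component comparator scores
#'
#' The five components (waist, blood pressure — mean arterial by default —
#' log triglycerides, HDL, glycemic variable) are standardized and the
#' principal components of their correlation matrix extracted. Two variants:
#' `pca_first_component` scores each subject on the first component;
#' `pca_weighted_sum` combines the first two components weighted by their
#' explained-variance fractions, \eqn{(\lambda_1 PC_1 + \lambda_2 PC_2) /
#' (\lambda_1 + \lambda_2)}. Components are retained by the
#' eigenvalue-greater-than-1 rule; when only one qualifies the weighted sum
#' degrades to the first component with a warning (common in age-homogeneous
#' strata). Each retained component is oriented so its waist loading is
#' non-negative, making results deterministic.
#'
#' @param cohort A `sims_cohort`.
#' @param spec A [comparator_spec()] with a PCA method.
#' @return A `comparator_result` as in [z_sum_score()]; diagnostics carry
#'   loadings and explained-variance fractions per stratum.
#' @export
pca_score <- function(cohort,
                      spec = comparator_spec("pca_weighted_sum", "glucose")) {
  stopifnot(inherits(cohort, "sims_cohort"),
            inherits(spec, "comparator_spec"),
            spec$method %in% c("pca_first_component", "pca_weighted_sum"))
  m <- comparator_matrix(cohort, spec)
  complete <- stats::complete.cases(m) & !is.na(cohort$age)
  strat <- stratum_index(cohort$age, spec$strata)
  labels <- stratum_labels(spec$strata)
  score <- rep(NA_real_, nrow(cohort))
  stratum_col <- rep(NA_character_, nrow(cohort))
  diagnostics <- list()

  for (k in seq_along(labels)) {
    idx <- which(complete & !is.na(strat) & strat == k)
    if (length(idx) == 0) next
    if (length(idx) <= ncol(m)) {
      stop("pca_score needs more complete cases than components (stratum ",
           labels[k], " has ", length(idx), ").", call. = FALSE)
    }
    x <- m[idx, , drop = FALSE]
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      stop("Constant component '", colnames(m)[which(sds == 0)[1]],
           "' in stratum ", labels[k], ".", call. = FALSE)
    }
    z <- scale(x)
    eig <- eigen(stats::cor(x), symmetric = TRUE)
    vec <- apply(eig$vectors, 2, orient_component)
    pcs <- z %*% vec
    frac <- eig$values / sum(eig$values)
    n_retained <- sum(eig$values > 1)
    if (spec$method == "pca_first_component") {
      s <- pcs[, 1]
    } else if (n_retained >= 2) {
      s <- (frac[1] * pcs[, 1] + frac[2] * pcs[, 2]) / (frac[1] + frac[2])
    } else {
      warning("Only one factor extracted in stratum ", labels[k],
              "; weighted sum falls back to the first component.",
              call. = FALSE)
      s <- pcs[, 1]
    }
    score[idx] <- s
    stratum_col[idx] <- labels[k]
    diagnostics[[labels[k]]] <- list(
      n = length(idx),
      loadings = structure(vec, dimnames = list(colnames(m),
                                                paste0("PC", seq_len(ncol(vec))))),
      explained_variance = frac,
      n_factors_retained = n_retained
    )
  }

  structure(list(
    scores = tibble::tibble(subject_id = cohort$subject_id, score = score,
                            stratum = stratum_col),
    label = spec$label, spec = spec, diagnostics = diagnostics
  ), class = "comparator_result")
}

#' Compute any comparator score
#'
#' Dispatches a [comparator_spec()] to [z_sum_score()] or [pca_score()].
#' @inheritParams z_sum_score
#' @return A `comparator_result`.
#' @export
compute_comparator <- function(cohort, spec) {
  stopifnot(inherits(spec, "comparator_spec"))
  if (spec$method == "z_sum") z_sum_score(cohort, spec)
  else pca_score(cohort, spec)
}

#' @export
print.comparator_result <- function(x, ...) {
  cat("Comparator score:", x$label, "\n")
  cat("  complete cases:", sum(!is.na(x$scores$score)), "of",
      nrow(x$scores), "\n")
  for (lab in names(x$diagnostics)) {
    d <- x$diagnostics[[lab]]
    cat("  stratum ", lab, ": n = ", d$n, sep = "")
    if (!is.null(d$n_factors_retained)) {
      cat(", factors retained = ", d$n_factors_retained, sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' Export comparator diagnostics as a tidy table
#'
#' @param result A `comparator_result`.
#' @return A tibble of per-stratum diagnostics (coefficients or loadings),
#'   suitable for CSV export.
#' @export
comparator_diagnostics <- function(result) {
  stopifnot(inherits(result, "comparator_result"))
  rows <- list()
  for (lab in names(result$diagnostics)) {
    d <- result$diagnostics[[lab]]
    if (!is.null(d$loadings)) {
      for (pc in colnames(d$loadings)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          stratum = lab, component = rownames(d$loadings),
          quantity = pc, value = d$loadings[, pc])
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        stratum = lab, component = paste0("PC", seq_along(d$explained_variance)),
        quantity = "explained_variance_fraction",
        value = d$explained_variance)
    } else {
      for (comp in names(d$coefficients)) {
        co <- d$coefficients[[comp]]
        rows[[length(rows) + 1]] <- tibble::tibble(
          stratum = lab, component = comp,
          quantity = names(co), value = unname(co))
      }
    }
  }
  dplyr::bind_rows(rows)
}
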