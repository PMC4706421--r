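# Shared fixture builders. All fixtures are built in code at test time.

# Minimal complete subject rows with overridable fields.
make_subjects <- function(n = 3, ...) {
  base <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    sex = rep(c("female", "male"), length.out = n),
    age = seq(30, by = 2, length.out = n),
    height = rep(170, n), weight = rep(80, n), waist = rep(95, n),
    systolic_bp = rep(125, n), diastolic_bp = rep(80, n),
    glucose = rep(5.2, n), insulin = rep(12, n),
    triglycerides = rep(1.6, n), hdl = rep(1.2, n),
    family_history_cv = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

make_cohort <- function(n = 3, ...) {
  as_cohort(make_subjects(n, ...))
}

# A random fully complete cohort for oracle comparisons (direct construction,
# independent of the package generator).
random_cohort <- function(n, seed) {
  set.seed(seed)
  df <- data.frame(
    subject_id = sprintf("r%03d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = runif(n, 18, 70),
    height = rnorm(n, 170, 8),
    weight = rnorm(n, 82, 12),
    waist = rnorm(n, 95, 12),
    systolic_bp = rnorm(n, 128, 12),
    diastolic_bp = rnorm(n, 82, 8),
    glucose = rnorm(n, 5.4, 0.6),
    insulin = exp(rnorm(n, log(11), 0.4)),
    triglycerides = exp(rnorm(n, log(1.6), 0.3)),
    hdl = rnorm(n, 1.25, 0.2),
    family_history_cv = runif(n) < 0.3,
    stringsAsFactors = FALSE
  )
  df$diastolic_bp <- pmin(df$diastolic_bp, df$systolic_bp - 5)
  df$hdl <- pmax(df$hdl, 0.5)
  as_cohort(df)
}

# The printed two-decimal score columns for the ten worked-example subjects,
# in table2_fixture() row order.
table2_printed <- function() {
  tibble::tibble(
    subject_id = c("p1_baseline", "p1_followup", "p2_baseline", "p2_followup",
                   "p3_baseline", "p3_followup", "p4_baseline", "p4_followup",
                   "p5_baseline", "p5_followup"),
    sims = c(4.28, 2.92, 3.37, 3.17, 3.90, 3.13, 3.46, 3.01, 3.18, 2.91),
    risk = c(2.05, 1.54, 2.69, 3.12, 4.14, 3.38, 3.49, 3.76, 2.54, 2.52)
  )
}
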