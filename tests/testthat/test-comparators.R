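# Independent z-sum oracle: normal-equations OLS, manual standardization.
oracle_z_sum <- function(cohort, glycemic = "glucose") {
  g <- switch(glycemic,
    glucose = cohort$glucose,
    insulin = log(cohort$insulin),
    homa = log(cohort$insulin * cohort$glucose / 22.5))
  comps <- cbind(cohort$waist, cohort$systolic_bp, log(cohort$triglycerides),
                 cohort$hdl, g)
  X <- cbind(1, cohort$age, as.numeric(cohort$sex == "male"))
  z <- sapply(seq_len(ncol(comps)), function(j) {
    y <- comps[, j]
    beta <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% beta
    (res - mean(res)) / sd(res)
  })
  z[, 4] <- -z[, 4]
  rowSums(z)
}

test_that("z-sum scores match a normal-equations oracle to 1e-10", {
  for (seed in 1:5) {
    n <- sample(10:50, 1)
    co <- random_cohort(n, seed = 200 + seed)
    for (gl in c("glucose", "insulin", "homa")) {
      got <- z_sum_score(co, comparator_spec("z_sum", gl))$scores$score
      expect_equal(got, oracle_z_sum(co, gl), tolerance = 1e-10,
                   label = paste("seed", seed, gl))
    }
  }
})

test_that("a two-subject stratum gives the closed-form +/- 5/sqrt(2) scores", {
  df <- make_subjects(2, sex = "female", age = 40)
  # subject 1 worse on all five components
  df$waist <- c(110, 90)
  df$systolic_bp <- c(145, 115)
  df$triglycerides <- c(2.6, 1.2)
  df$hdl <- c(0.9, 1.6)
  df$glucose <- c(6.2, 4.9)
  expect_warning(z_sum_score(as_cohort(df)), "constant")
  res <- suppressWarnings(z_sum_score(as_cohort(df)))
  expect_equal(res$scores$score, c(5, -5) / sqrt(2), tolerance = 1e-12)
})

test_that("z-sum is invariant to affine rescaling of raw components", {
  co <- random_cohort(30, seed = 11)
  base <- z_sum_score(co)$scores$score
  rescaled <- co
  rescaled$waist <- rescaled$waist * 2.54       # linear component
  rescaled$triglycerides <- rescaled$triglycerides * 88.5  # log component
  expect_equal(z_sum_score(rescaled)$scores$score, base, tolerance = 1e-10)
})

test_that("stratified z-sums standardize independently within each stratum", {
  co <- generate_cohort(synthetic_config(n = 300, seed = 9))
  res <- z_sum_score(co, comparator_spec("z_sum", "glucose",
                                         strata = age_strata_default()))
  sc <- res$scores
  expect_setequal(unique(stats::na.omit(sc$stratum)),
                  c("[0,18)", "[18,31)", "[31,Inf)"))
  for (lab in unique(stats::na.omit(sc$stratum))) {
    expect_equal(mean(sc$score[!is.na(sc$stratum) & sc$stratum == lab]), 0,
                 tolerance = 1e-8)
  }
})

# Independent PCA oracle via singular value decomposition.
oracle_pca <- function(cohort, method, glycemic = "glucose") {
  g <- switch(glycemic,
    glucose = cohort$glucose,
    homa = log(cohort$insulin * cohort$glucose / 22.5))
  mapv <- cohort$diastolic_bp +
    (cohort$systolic_bp - cohort$diastolic_bp) / 3
  x <- cbind(cohort$waist, mapv, log(cohort$triglycerides), cohort$hdl, g)
  z <- scale(x)
  sv <- svd(z)
  lambda <- sv$d^2 / (nrow(z) - 1)
  v <- sv$v
  for (j in seq_len(ncol(v))) {
    pivot <- if (v[1, j] != 0) v[1, j] else v[3, j]
    if (pivot < 0) v[, j] <- -v[, j]
  }
  pcs <- z %*% v
  frac <- lambda / sum(lambda)
  if (method == "pca_first_component" || sum(lambda > 1) < 2) {
    pcs[, 1]
  } else {
    (frac[1] * pcs[, 1] + frac[2] * pcs[, 2]) / (frac[1] + frac[2])
  }
}

test_that("PCA scores match an independent SVD oracle to 1e-8", {
  for (seed in 1:5) {
    n <- sample(15:50, 1)
    co <- random_cohort(n, seed = 300 + seed)
    for (method in c("pca_first_component", "pca_weighted_sum")) {
      got <- suppressWarnings(
        pca_score(co, comparator_spec(method, "glucose"))$scores$score)
      expect_equal(got, oracle_pca(co, method), tolerance = 1e-8,
                   label = paste("seed", seed, method))
    }
  }
})

test_that("perfectly correlated components collapse onto one component", {
  set.seed(42)
  v <- rnorm(12)
  df <- make_subjects(12)
  df$waist <- 95 + 5 * v
  bp <- 100 + 6 * v
  df$systolic_bp <- bp + 20
  df$diastolic_bp <- bp - 10   # MAP = bp (10/3 offset), affine in v
  df$triglycerides <- exp(0.4 + 0.2 * v)
  df$hdl <- 1.2 + 0.1 * v
  df$glucose <- 5.3 + 0.5 * v
  expect_warning(pca_score(as_cohort(df)), "one factor")
  res <- suppressWarnings(pca_score(as_cohort(df)))
  d <- res$diagnostics$all
  expect_equal(d$explained_variance[1], 1, tolerance = 1e-10)
  # score is the common column up to positive scale
  s <- res$scores$score
  expect_equal(cor(s, v), 1, tolerance = 1e-10)
})

test_that("first-component scores have mean 0 and variance lambda1", {
  co <- random_cohort(60, seed = 5)
  res <- pca_score(co, comparator_spec("pca_first_component", "glucose"))
  s <- res$scores$score
  f1 <- res$diagnostics$all$explained_variance[1]
  expect_equal(mean(s), 0, tolerance = 1e-6)
  expect_equal(stats::var(s), f1 * 5, tolerance = 1e-6)
})

test_that("comparator runs are deterministic and bit-identical", {
  co <- generate_cohort(synthetic_config(n = 120, seed = 13))
  a <- z_sum_score(co)
  b <- z_sum_score(co)
  expect_identical(a$scores, b$scores)
  pa <- pca_score(co)
  pb <- pca_score(co)
  expect_identical(pa$scores, pb$scores)
})

test_that("single-factor cohorts trigger the one-factor fallback and agree", {
  # strongly coupled single-latent-factor population
  rs <- sapply(1:5, function(seed) {
    co <- generate_cohort(synthetic_config(n = 300, seed = seed,
                                           lipid_axis_scale = 0,
                                           severity_scale = 1.5))
    expect_warning(pca_score(co), "one factor")
    pw <- suppressWarnings(pca_score(co))$scores$score
    z <- z_sum_score(co)$scores$score
    cor(z, pw)
  })
  expect_true(all(rs > 0.9))
})

test_that("degenerate inputs are rejected with informative errors", {
  co <- random_cohort(4, seed = 1)
  expect_error(pca_score(co), "more complete cases than components")
  df <- make_subjects(10)
  df$age <- runif(10, 20, 60)
  con <- as_cohort(df)  # all components constant across subjects
  expect_error(z_sum_score(con), "zero residual variance")
  expect_error(pca_score(as_cohort(df)), "Constant component")
})

test_that("diagnostics export as a tidy table", {
  co <- random_cohort(40, seed = 21)
  d1 <- comparator_diagnostics(z_sum_score(co))
  expect_true(all(c("stratum", "component", "quantity", "value") %in%
                    names(d1)))
  d2 <- comparator_diagnostics(suppressWarnings(pca_score(co)))
  expect_true("explained_variance_fraction" %in% d2$quantity)
})
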