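test_that("adult component flags flip exactly at the quoted cutoffs", {
  eps <- 1e-9
  cases <- list(
    # column, male value at/below cutoff, female value, flag, direction
    list(col = "waist", m = 94, f = 80, flag = "waist_flag", geq = TRUE),
    list(col = "triglycerides", m = 1.7, f = 1.7, flag = "tg_flag",
         geq = TRUE),
    list(col = "hdl", m = 1.03, f = 1.29, flag = "hdl_flag", geq = FALSE),
    list(col = "systolic_bp", m = 130, f = 130, flag = "bp_flag",
         geq = TRUE),
    list(col = "glucose", m = 5.6, f = 5.6, flag = "glucose_flag",
         geq = TRUE)
  )
  for (case in cases) {
    for (sx in c("male", "female")) {
      cut <- if (sx == "male") case$m else case$f
      at <- make_subjects(1, sex = sx)
      at[[case$col]] <- cut
      below <- at
      below[[case$col]] <- cut - eps
      flag_at <- classify_adult(as_cohort(at))[[case$flag]]
      flag_below <- classify_adult(as_cohort(below))[[case$flag]]
      if (case$geq) {
        expect_true(flag_at, label = paste(case$col, sx, "at cutoff"))
        expect_false(flag_below, label = paste(case$col, sx, "below"))
      } else {
        # reduced HDL is a strict < comparison
        expect_false(flag_at, label = paste(case$col, sx, "at cutoff"))
        expect_true(flag_below, label = paste(case$col, sx, "below"))
      }
    }
  }
  # the diastolic arm of the blood pressure criterion
  d_at <- make_subjects(1, systolic_bp = 120, diastolic_bp = 85)
  d_below <- make_subjects(1, systolic_bp = 120, diastolic_bp = 84.99)
  expect_true(classify_adult(as_cohort(d_at))$bp_flag)
  expect_false(classify_adult(as_cohort(d_below))$bp_flag)
})

test_that("threshold application reproduces the worked borderline subject", {
  # male with waist 104, Tg 2.09, HDL exactly 1.03, BP 140/80, glucose 5.5
  co <- make_cohort(1, sex = "male", age = 30, waist = 104,
                    triglycerides = 2.09, hdl = 1.03, systolic_bp = 140,
                    diastolic_bp = 80, glucose = 5.5)
  cls <- classify_adult(co)
  expect_true(cls$waist_flag)
  expect_true(cls$tg_flag)
  expect_false(cls$hdl_flag)  # 1.03 is not < 1.03
  expect_true(cls$bp_flag)
  expect_false(cls$glucose_flag)
  expect_equal(cls$n_components, 3L)
  expect_true(cls$ms_present)
  expect_equal(component_count(co), 3L)
})

test_that("values just below every cutoff give zero components", {
  co <- make_cohort(1, sex = "female", waist = 79, triglycerides = 1.6,
                    hdl = 1.30, systolic_bp = 129, diastolic_bp = 84,
                    glucose = 5.5)
  cls <- classify_adult(co)
  expect_equal(cls$n_components, 0L)
  expect_false(cls$ms_present)
})

test_that("treatment flags count as fulfilled criteria and only ever add", {
  co <- make_cohort(1, sex = "female", waist = 85, triglycerides = 1.0,
                    hdl = 1.6, systolic_bp = 110, diastolic_bp = 70,
                    glucose = 4.8, treated_lipids = TRUE, treated_bp = TRUE)
  cls <- classify_adult(co)
  expect_true(cls$tg_flag)
  expect_true(cls$bp_flag)
  expect_equal(cls$n_components, 3L)  # waist 85 >= 80 plus two treated
  expect_true(cls$ms_present)

  # dominance property: turning any treatment flag on never lowers the count
  for (seed in 1:5) {
    co <- random_cohort(20, seed = seed)
    base_count <- classify_adult(co)$n_components
    for (flag in c("treated_lipids", "treated_bp", "treated_glucose",
                   "treated_hdl")) {
      treated <- co
      treated[[flag]] <- TRUE
      expect_true(all(classify_adult(treated)$n_components >= base_count))
    }
  }
})

test_that("worsening any single component never decreases the count", {
  worsen <- list(waist = 1.3, triglycerides = 1.5, hdl = 0.6,
                 systolic_bp = 1.2, glucose = 1.3)
  for (seed in 1:5) {
    co <- random_cohort(15, seed = 100 + seed)
    base_count <- classify_adult(co)$n_components
    for (col in names(worsen)) {
      bad <- co
      bad[[col]] <- bad[[col]] * worsen[[col]]
      expect_true(all(classify_adult(bad)$n_components >= base_count),
                  label = col)
    }
  }
})

test_that("missing components leave the diagnosis missing when ambiguous", {
  # 2 true, 2 false, 1 missing: cannot decide >= 3
  co <- make_cohort(1, sex = "male", waist = 100, triglycerides = 2.0,
                    hdl = NA, systolic_bp = 120, diastolic_bp = 75,
                    glucose = 5.0)
  cls <- classify_adult(co)
  expect_true(is.na(cls$hdl_flag))
  expect_true(is.na(cls$ms_present))
  expect_true(is.na(cls$n_components))
  # 3 true and 1 missing: decidable despite the gap
  co2 <- make_cohort(1, sex = "male", waist = 100, triglycerides = 2.0,
                     hdl = NA, systolic_bp = 135, diastolic_bp = 75,
                     glucose = 5.7)
  expect_true(classify_adult(co2)$ms_present)
  expect_true(is.na(classify_adult(co2)$n_components))
})

test_that("pediatric rule: mandatory waist plus two others, ages 10 to <16", {
  ped <- pediatric_reference()
  # female age 12, default synthetic p90 = 75 cm
  base <- make_cohort(1, sex = "female", age = 12, waist = 80,
                      triglycerides = 2.0, hdl = 1.2, systolic_bp = 110,
                      diastolic_bp = 70, glucose = 5.0)
  cls <- classify_pediatric(base, ped)
  expect_true(cls$waist_flag)
  expect_false(cls$ms_present)  # waist + only one other criterion (Tg)
  with_gly <- make_cohort(1, sex = "female", age = 12, waist = 80,
                          triglycerides = 2.0, hdl = 1.2, systolic_bp = 110,
                          diastolic_bp = 70, glucose = 5.7)
  expect_true(classify_pediatric(with_gly, ped)$ms_present)
  # abdominal obesity is mandatory: same abnormalities, slim waist
  slim <- make_cohort(1, sex = "female", age = 12, waist = 60,
                      triglycerides = 2.0, hdl = 1.0, systolic_bp = 135,
                      diastolic_bp = 70, glucose = 5.7)
  expect_false(classify_pediatric(slim, ped)$ms_present)
})

test_that("pediatric path hands 16+ to the adult rule and refuses under-10s", {
  vals <- list(sex = "female", waist = 85, triglycerides = 1.9, hdl = 1.1,
               systolic_bp = 132, diastolic_bp = 80, glucose = 5.0)
  seventeen <- do.call(make_cohort, c(list(n = 1, age = 17), vals))
  adult_like <- do.call(make_cohort, c(list(n = 1, age = 30), vals))
  expect_equal(classify_pediatric(seventeen)[-1], classify_adult(adult_like)[-1])
  eight <- do.call(make_cohort, c(list(n = 1, age = 8), vals))
  expect_warning(classify_pediatric(eight), "not defined")
  cls <- suppressWarnings(classify_pediatric(eight))
  expect_true(is.na(cls$ms_present))
  expect_true(all(is.na(cls$n_components)))
})

test_that("classify_ms dispatches by age and preserves row order", {
  df <- make_subjects(4, age = c(45, 17, 12, 8))
  cls <- suppressWarnings(classify_ms(as_cohort(df)))
  expect_identical(cls$subject_id, df$subject_id)
  expect_false(anyNA(cls$ms_present[1:2]))
  expect_true(is.na(cls$ms_present[4]))
})
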