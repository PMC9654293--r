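test_that("cohort generation is byte-identical under the same seed", {
  a <- generate_cohort(cohort_spec(n_patients = 40, seed = 33))
  b <- generate_cohort(cohort_spec(n_patients = 40, seed = 33))
  expect_identical(a$patients, b$patients)
  expect_identical(a$measures, b$measures)
  c <- generate_cohort(cohort_spec(n_patients = 40, seed = 34))
  expect_false(identical(a$patients, c$patients))
})

test_that("planted effects on unknown measures are a schema error", {
  expect_error(cohort_spec(planted_effects = c(XYZ = 0.2)), "unknown measure")
  expect_error(cohort_spec(confounder_effects = c(bmi = 1)), "confounders")
  expect_error(cohort_spec(n_patients = 1), "n_patients")
  expect_error(cohort_spec(missingness = c(albumin = 1.2)), "missingness")
  expect_error(cohort_spec(followup_years_range = c(-1, 2)), "followup")
})

test_that("simulated marginals track their targets", {
  co <- generate_cohort(cohort_spec(n_patients = 4000, seed = 8))
  p <- co$patients
  expect_equal(mean(p$age), 63.41, tolerance = 0.02)
  expect_equal(mean(p$sex == "F"), 0.5204, tolerance = 0.05)
  expect_equal(mean(p$deceased), 0.337, tolerance = 0.1)
  expect_equal(mean(p$has_followup), 61 / 98, tolerance = 0.05)
  base <- co$truth$baseline
  expect_equal(mean(base[, "NDMA"]), 23.67, tolerance = 0.05)
  expect_equal(mean(base[, "SFA"]), 66.59, tolerance = 0.05)
})

test_that("death-cause labels exist only for the deceased, at stated rates", {
  co <- generate_cohort(cohort_spec(n_patients = 3000, seed = 4))
  p <- co$patients
  expect_true(all(is.na(p$death_cause[p$deceased == 0])))
  expect_true(all(!is.na(p$death_cause[p$deceased == 1])))
  causes <- table(p$death_cause) / sum(p$deceased)
  expect_equal(unname(causes["tumor"]), 0.70, tolerance = 0.1)
})

test_that("every rater record satisfies the fat and muscle additivity", {
  co <- generate_cohort(cohort_spec(n_patients = 25, seed = 6))
  m <- co$measures
  wide <- reshape(m, idvar = c("patient_id", "timepoint", "rater"),
                  timevar = "measure", direction = "wide")
  names(wide) <- sub("^area_cm2\\.", "", names(wide))
  expect_equal(wide$TFA, wide$SFA + wide$VFA + wide$IMFA, tolerance = 1e-3)
  expect_equal(wide$TMA,
               wide$VLDM + wide$LDMA + wide$NDMA + wide$HDMA + wide$VHDMA,
               tolerance = 1e-3)
})

test_that("follow-up measurements exist exactly for follow-up patients", {
  co <- generate_cohort(cohort_spec(n_patients = 60, seed = 9))
  fup_ids <- sort(unique(co$measures$patient_id[
    co$measures$timepoint == "followup"]))
  expect_identical(fup_ids,
                   sort(co$patients$patient_id[co$patients$has_followup]))
  expect_true(all(diff(c(0, sum(co$patients$has_followup),
                         nrow(co$patients))) > 0))  # strict subset
})
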