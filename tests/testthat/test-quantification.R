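rec_of <- function(values, patient = "P1", tp = "diagnosis", height = 1.7,
                   date = as.Date("2010-01-01")) {
  composition_record(patient, tp, "A", area_cm2 = values, height_m = height,
                     acquisition_date = date)
}

test_that("height normalization divides by squared height", {
  r <- normalize_by_height(rec_of(c(SFA = 100), height = 2.0))
  expect_equal(r$area_norm[["SFA"]], 25)
  r1 <- normalize_by_height(rec_of(c(SFA = 87.3), height = 1.0))
  expect_equal(r1$area_norm, r1$area_cm2)     # height 1: identity
  expect_error(normalize_by_height(rec_of(c(SFA = 1), height = NA)),
               "height")
  expect_error(normalize_by_height(rec_of(c(SFA = 1), height = 2.6)),
               "height")
})

test_that("normalization matches independent recomputation on random records", {
  set.seed(21)
  areas <- matrix(runif(500 * 3, 0, 300), 500,
                  dimnames = list(NULL, c("SFA", "VFA", "TMA")))
  heights <- runif(500, 1.4, 2.0)
  for (i in sample(500, 25)) {            # spot-check a sample of records
    r <- normalize_by_height(rec_of(areas[i, ], height = heights[i]))
    expect_equal(unname(r$area_norm), unname(areas[i, ]) / heights[i]^2)
  }
  # data.frame method agrees with the record method
  df <- data.frame(patient_id = sprintf("P%03d", 1:500),
                   measure = "SFA", area_cm2 = areas[, "SFA"])
  pts <- data.frame(patient_id = df$patient_id, height_m = heights)
  out <- normalize_by_height(df, pts)
  expect_equal(out$area_norm, areas[, "SFA"] / heights^2)
})

test_that("the reliability gate retains on strict rho > threshold", {
  mk <- function(a, b, measure = "M") {
    data.frame(measure = measure, patient_id = seq_along(a),
               timepoint = "diagnosis", value_a = a, value_b = b)
  }
  g <- reliability_gate(mk(1:10, (1:10) * 3 + 2))   # monotone: rho = 1
  expect_true(g$retained)
  expect_equal(g$rho, 1)
  g2 <- reliability_gate(mk(1:10, 10:1))            # reversed: rho = -1
  expect_false(g2$retained)
  expect_equal(g2$rho, -1)
  g3 <- reliability_gate(mk(1:10, rep(5, 10)))      # constant: undefined
  expect_false(g3$retained)
  expect_match(g3$reason, "constant")
  # rho exactly at the threshold is dropped ("greater than" is strict)
  set.seed(9)
  repeat {
    a <- rnorm(40); b <- a + rnorm(40)
    rho <- cor(a, b, method = "spearman")
    if (rho < 0.999) break
  }
  expect_false(reliability_gate(mk(a, b), threshold = rho)$retained)
  expect_true(reliability_gate(mk(a, b), threshold = rho - 1e-9)$retained)
})

test_that("the gate is invariant to patient order", {
  co <- generate_cohort(cohort_spec(n_patients = 40, seed = 3))
  norm <- normalize_by_height(co$measures, co$patients)
  pairs <- make_rater_pairs(norm)
  g1 <- reliability_gate(pairs)
  perm <- pairs[sample(nrow(pairs)), ]
  g2 <- reliability_gate(perm)
  expect_equal(g1, g2, ignore_attr = TRUE)
})

test_that("only the degraded measure fails the gate on a synthetic cohort", {
  # body_area feeds no total, so degrading it cannot drag a sum down with it
  co <- generate_cohort(cohort_spec(n_patients = 300, seed = 17,
                                    degraded_measure = "body_area",
                                    degraded_rho = 0.6))
  q <- quantify_cohort(co$measures, co$patients)
  expect_identical(q$gate$measure[!q$gate$retained], "body_area")
  expect_lt(q$gate$rho[q$gate$measure == "body_area"], 0.85)
})

test_that("rater averaging is the arithmetic mean and commutes with normalization", {
  a <- rec_of(c(SFA = 10, TMA = 40))
  b <- rec_of(c(SFA = 20, TMA = 44))
  m <- average_raters(a, b)
  expect_equal(m$area_cm2, c(SFA = 15, TMA = 42))
  expect_identical(m$rater_id, "mean")
  expect_equal(average_raters(a, a)$area_cm2, a$area_cm2)
  # normalize-then-average equals average-then-normalize (same height)
  na <- normalize_by_height(a); nb <- normalize_by_height(b)
  expect_equal(average_raters(na, nb)$area_norm,
               normalize_by_height(average_raters(a, b))$area_norm)
})

test_that("follow-up deltas respect the one-year rule and sign convention", {
  init <- normalize_by_height(rec_of(c(LDMA = 12.07 * 1.7^2),
                                     date = as.Date("2010-01-01")))
  fin <- normalize_by_height(rec_of(c(LDMA = 13.41 * 1.7^2), tp = "followup",
                                    date = as.Date("2012-06-01")))
  d <- compute_delta(init, fin)
  expect_false(d$excluded)
  expect_equal(d$delta[["LDMA"]], 1.34, tolerance = 1e-10)  # gain positive

  early <- normalize_by_height(rec_of(c(LDMA = 20), tp = "followup",
                                      date = as.Date("2010-07-01")))
  d2 <- compute_delta(init, early)                # 0.5 y: excluded
  expect_true(d2$excluded)
  expect_match(d2$reason, "interval")
  expect_null(d2$delta)

  same <- normalize_by_height(rec_of(c(LDMA = 12.07 * 1.7^2),
                                     tp = "followup",
                                     date = as.Date("2012-01-02")))
  expect_equal(compute_delta(init, same)$delta[["LDMA"]], 0)

  expect_error(compute_delta(fin, init), "chronology")
  expect_error(compute_delta(rec_of(c(LDMA = 1)), fin), "normalized")
})

test_that("missingness filter drops strictly above 40%", {
  df <- data.frame(patient_id = 1:100,
                   a = c(rep(NA, 41), rnorm(59)),      # 41%
                   b = c(rep(NA, 40), rnorm(60)),      # exactly 40%
                   deceased = rbinom(100, 1, 0.3))
  out <- missingness_filter(df)
  expect_identical(out$dropped$variable, "a")
  expect_true("b" %in% names(out$table))
  expect_equal(nrow(out$table), 100)                   # never drops patients
  # protected columns are kept even if fully missing
  df$death_cause <- NA_character_
  expect_false("death_cause" %in%
                 missingness_filter(df)$dropped$variable)
})

test_that("deltas of an unchanging cohort are centred on zero", {
  drift0 <- default_drift()
  drift0$mean <- 0; drift0$sd <- 0
  means <- vapply(1:8, function(s) {
    co <- generate_cohort(cohort_spec(n_patients = 80, seed = s,
                                      drift = drift0, followup_prob = 1))
    q <- quantify_cohort(co$measures, co$patients)
    mean(q$delta$delta_NDMA)
  }, numeric(1))
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)) + 0.05)
})

test_that("quantified patients are conserved between deltas and exclusions", {
  co <- generate_cohort(cohort_spec(n_patients = 70, seed = 12))
  q <- quantify_cohort(co$measures, co$patients)
  expect_equal(nrow(q$delta) + nrow(q$excluded), nrow(q$baseline))
})
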