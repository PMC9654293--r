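test_that("hugrid header and values parse into a calibrated slice", {
  f <- tempfile(fileext = ".hugrid")
  writeLines(c("2 2 1.0 1.0", "0 0", "0 0"), f)
  s <- read_slice(f, patient_id = "w")
  expect_identical(dim(s$hu), c(2L, 2L))
  expect_true(all(s$hu == 0))           # water-equivalent
  expect_equal(s$pixel_spacing, c(1, 1))
})

test_that("slice construction enforces calibration invariants", {
  expect_error(hu_slice(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(hu_slice(matrix(0, 2, 2), pixel_spacing = c(0, 1)), "positive")
  expect_error(hu_slice(matrix(5000, 2, 2)), "range")
  # fractional HU rounded once, ties away from zero
  s <- hu_slice(matrix(c(0.5, -0.5, 1.2, -1.2), 2), c(1, 1))
  expect_identical(as.vector(s$hu), c(1L, -1L, 1L, -1L))
})

test_that("DICOM calibration maps stored 1024 with intercept -1024 to HU 0", {
  s <- hu_slice(matrix(0L, 4, 3), c(0.9, 1.1), patient_id = "cal")
  f <- tempfile(fileext = ".dcm")
  write_slice(s, f)                     # writer uses intercept -1024, slope 1
  r <- read_slice(f)
  expect_true(all(r$hu == 0L))
  expect_equal(r$pixel_spacing, c(0.9, 1.1))
  expect_identical(r$patient_id, "cal")
})

test_that("slice write/read round trips are value-identical in all formats", {
  ph <- generate_phantom(small_phantom_spec(tissue_hu_sd = 5, seed = 11))
  for (ext in c(".hugrid", ".nii", ".dcm")) {
    f <- tempfile(fileext = ext)
    write_slice(ph$slice, f)
    r <- read_slice(f, patient_id = "phantom")
    expect_identical(r$hu, ph$slice$hu, label = ext)
    expect_equal(r$pixel_spacing, ph$slice$pixel_spacing)
    # idempotent: a second read gives the same grid
    expect_identical(read_slice(f, patient_id = "phantom")$hu, r$hu)
  }
})

test_that("the DICOM reader agrees with an independently written file", {
  vals <- matrix(sample(-200:300, 30), 6, 5)
  f <- write_pydicom_fixture(tempfile(fileext = ".dcm"), vals)
  expect_false(is.null(f))
  s <- read_slice(f)
  expect_identical(unname(s$hu), vals + 0L)
  expect_equal(s$pixel_spacing, c(0.8, 0.7))
  expect_identical(s$patient_id, "PYFIX")
})

test_that("missing rescale tags are a calibration error unless overridden", {
  vals <- matrix(0L, 3, 3)
  f <- write_pydicom_fixture(tempfile(fileext = ".dcm"), vals,
                             intercept = 0, with_rescale = FALSE)
  expect_false(is.null(f))
  expect_error(read_slice(f), "rescale")
  s <- read_slice(f, assume_identity_rescale = TRUE)
  expect_true(all(s$hu == 0L))
})

test_that("3-D volumes are rejected with instruction to extract the slice", {
  f <- tempfile(fileext = ".nii")
  arr <- array(0L, dim = c(8, 8, 4))
  RNifti::writeNifti(RNifti::asNifti(arr), f)
  expect_error(read_slice(f), "L3 slice")
  # trailing singleton dimensions are fine
  f2 <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(7L, dim = c(8, 8, 1))), f2)
  expect_true(all(read_slice(f2)$hu == 7L))
})

test_that("cohort CSV round trip preserves values and duplicate keys error", {
  co <- generate_cohort(cohort_spec(n_patients = 12, seed = 5))
  d <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(back$measures$area_cm2, co$measures$area_cm2)
  expect_equal(back$patients$age, co$patients$age)
  expect_s3_class(back$patients$diagnosis_date, "Date")
  expect_equal(back$patients$diagnosis_date, co$patients$diagnosis_date)
  # corrupt: duplicate a measurement row
  m <- utils::read.csv(file.path(d, "measures.csv"), na.strings = "")
  utils::write.csv(rbind(m, m[1, ]), file.path(d, "measures.csv"),
                   row.names = FALSE, na = "")
  expect_error(read_cohort(d), "integrity")
})

test_that("all-missing optional columns survive reading until the filter", {
  co <- generate_cohort(cohort_spec(n_patients = 8, seed = 2,
                                    missingness = c(chromogranin_a = 1)))
  d <- file.path(tempdir(), "cohort_allmiss")
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_true("chromogranin_a" %in% names(back$patients))
  expect_true(all(is.na(back$patients$chromogranin_a)))
  filt <- missingness_filter(back$patients)
  expect_true("chromogranin_a" %in% filt$dropped$variable)
})
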