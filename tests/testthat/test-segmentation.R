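test_that("an all-air slice is a segmentation failure", {
  s <- hu_slice(matrix(-1000L, 32, 32), c(1, 1))
  expect_error(compute_body_mask(s), "segmentation failure")
})

test_that("a detached low-density blob does not change the body mask", {
  ph <- generate_phantom(small_phantom_spec())
  base <- compute_body_mask(ph$slice)
  hu <- ph$slice$hu
  hu[2:4, 2:5] <- -200L                  # 12-px scanner-table blob
  withblob <- compute_body_mask(hu_slice(hu, ph$slice$pixel_spacing))
  expect_identical(withblob, base)
})

test_that("the body mask recovers the phantom body raster exactly", {
  ph <- generate_phantom(small_phantom_spec())
  expect_identical(compute_body_mask(ph$slice), ph$masks$body)
})

test_that("zero-noise phantoms are recovered pixel-exactly", {
  for (ls in c(1, 2, 3)) {
    ph <- generate_phantom(small_phantom_spec(layout_seed = ls))
    body <- compute_body_mask(ph$slice)
    masks <- separate_compartments(ph$slice, body)
    expect_identical(masks$musclewall_region,
                     ph$masks$wall, label = paste("wall", ls))
    expect_identical(masks$visceral_region, ph$masks$cavity)
    expect_identical(masks$subcut_region, ph$masks$subcut)
    rec <- quantify_slice(ph$slice, masks)
    expect_identical(unname(rec$area_cm2), unname(ph$truth))
    expect_gt(rec$area_cm2[["IMFA"]], 0)  # speckle counted as IMFA
  }
})

test_that("a body without muscle-band pixels degenerates to subcutaneous", {
  hu <- matrix(-1000L, 64, 64)
  hu[20:44, 20:44] <- -100L              # pure fat block
  s <- hu_slice(hu, c(1, 1))
  body <- compute_body_mask(s)
  expect_warning(masks <- separate_compartments(s, body), "subcutaneous")
  expect_identical(masks$subcut_region, body)
  expect_false(any(masks$visceral_region))
  rec <- quantify_slice(s, masks)
  expect_equal(rec$area_cm2[["VFA"]], 0)
  expect_equal(rec$area_cm2[["TMA"]], 0)
})

test_that("band bounds are inclusive at the printed window edges", {
  hu <- matrix(c(-30L, -29L, 50L, -190L, -191L, 199L, 200L, 0L, 34L), 3, 3)
  s <- hu_slice(hu, c(1, 1))
  all_px <- matrix(TRUE, 3, 3)
  expect_equal(band_area(s, all_px, c(-190, -30)), 2 / 100)  # -30, -190
  expect_equal(band_area(s, all_px, c(-29, -1)), 1 / 100)    # -29 is VLDM
  expect_equal(band_area(s, all_px, c(0, 34)), 2 / 100)      # 0 and 34
  expect_equal(band_area(s, all_px, c(151, 199)), 1 / 100)   # 199 in, 200 out
})

test_that("band_area matches the per-pixel brute-force loop on random grids", {
  set.seed(401)
  for (k in 1:20) {
    hu <- matrix(sample(-300:260, 32 * 32, replace = TRUE), 32, 32)
    s <- hu_slice(hu, runif(2, 0.5, 2))
    region <- matrix(runif(32 * 32) < 0.5, 32, 32)
    band <- sort(sample(-250:220, 2))
    expect_equal(band_area(s, region, band), brute_band_area(s, region, band))
  }
})

test_that("muscle band areas sum exactly to the total muscle area", {
  set.seed(402)
  bands <- hu_band_table()
  muscle <- bands[bands$name != "fat", ]
  for (k in 1:10) {
    hu <- matrix(sample(-300:260, 40 * 40, replace = TRUE), 40, 40)
    s <- hu_slice(hu, c(1, 1))
    region <- matrix(runif(40 * 40) < 0.6, 40, 40)
    parts <- vapply(seq_len(nrow(muscle)), function(i)
      band_area(s, region, c(muscle$hu_low[i], muscle$hu_high[i])),
      numeric(1))
    expect_equal(sum(parts), band_area(s, region, attr(bands, "tma")),
                 tolerance = 1e-12)
  }
})

test_that("enlarging a region never decreases any band area", {
  set.seed(403)
  hu <- matrix(sample(-300:260, 30 * 30, replace = TRUE), 30, 30)
  s <- hu_slice(hu, c(1, 1))
  inner <- matrix(runif(900) < 0.3, 30, 30)
  outer <- inner | matrix(runif(900) < 0.3, 30, 30)
  for (band in list(c(-190, -30), c(-29, -1), c(35, 100), c(-29, 199)))
    expect_gte(band_area(s, outer, band), band_area(s, inner, band))
})

test_that("doubling pixel spacing quadruples every measure", {
  ph <- generate_phantom(small_phantom_spec())
  rec1 <- measure_slice(ph$slice)
  s2 <- hu_slice(ph$slice$hu, ph$slice$pixel_spacing * 2,
                 ph$slice$patient_id)
  rec2 <- measure_slice(s2)
  expect_equal(rec2$area_cm2, rec1$area_cm2 * 4)
})
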