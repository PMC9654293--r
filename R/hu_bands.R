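#' Hounsfield-unit band table for L3 body composition
#'
#' Returns the ordered table of inclusive integer HU windows that define the
#' body-composition measures: a single fat window (applied within the
#' subcutaneous, visceral and intermuscular compartments to yield SFA, VFA
#' and IMFA) and five muscle radiodensity windows that tile -29..199 HU
#' exactly (very low, low, normal, high and very high density), whose union
#' is the total muscle window (TMA).
#'
#' @param fat integer length-2, inclusive HU bounds of the fat window.
#' @param vldm,ldma,ndma,hdma,vhdma integer length-2 bounds of the five
#'   muscle windows. They must be contiguous and non-overlapping so that
#'   band areas add up to the total muscle area exactly.
#' @return A data.frame with columns `name`, `hu_low`, `hu_high` and an
#'   attribute `tma` holding the total-muscle window.
#' @examples
#' hu_band_table()
#' @export
hu_band_table <- function(fat   = c(-190L, -30L),
                          vldm  = c(-29L, -1L),
                          ldma  = c(0L, 34L),
                          ndma  = c(35L, 100L),
                          hdma  = c(101L, 150L),
                          vhdma = c(151L, 199L)) {
  bands <- rbind(
    data.frame(name = "fat",   hu_low = fat[1],   hu_high = fat[2]),
    data.frame(name = "VLDM",  hu_low = vldm[1],  hu_high = vldm[2]),
    data.frame(name = "LDMA",  hu_low = ldma[1],  hu_high = ldma[2]),
    data.frame(name = "NDMA",  hu_low = ndma[1],  hu_high = ndma[2]),
    data.frame(name = "HDMA",  hu_low = hdma[1],  hu_high = hdma[2]),
    data.frame(name = "VHDMA", hu_low = vhdma[1], hu_high = vhdma[2])
  )
  stopifnot(all(bands$hu_low <= bands$hu_high))
  muscle <- bands[bands$name != "fat", ]
  # the five muscle windows must tile their range with no gap or overlap,
  # otherwise TMA stops being the sum of its bands
  if (any(muscle$hu_low[-1] != muscle$hu_high[-nrow(muscle)] + 1L))
    stop("muscle bands must be contiguous and non-overlapping", call. = FALSE)
  attr(bands, "tma") <- c(muscle$hu_low[1], muscle$hu_high[nrow(muscle)])
  bands
}

#' Names of the body-composition measures
#'
#' The ten area measures produced by slice quantification, plus the total
#' body cross-sectional area.
#' @return Character vector of measure names.
#' @export
composition_measures <- function() {
  c("SFA", "VFA", "IMFA", "TFA",
    "VLDM", "LDMA", "NDMA", "HDMA", "VHDMA", "TMA",
    "body_area")
}

# measures that enter cohort analyses (body_area is carried alongside)
.delta_measures <- function() {
  c("body_area", "SFA", "VFA", "IMFA", "TFA",
    "VLDM", "LDMA", "NDMA", "HDMA", "VHDMA", "TMA")
}

#' Reference cohort summary used to calibrate the simulator
#'
#' Summary statistics of a published single-centre GEP-NET cohort
#' (98 patients included of 159 screened, 61 with a follow-up CT at least
#' one year after diagnosis) that the synthetic-cohort generator targets:
#' recruitment-flow counts, sex split by survival status, and the
#' height-normalized composition means/SDs (cm2/m2). These values are data
#' inputs to the simulation, not quantities the package estimates.
#'
#' @return A list with elements `flow` (screened/included/followup counts),
#'   `sex` (female counts among survivors/non-survivors and total N),
#'   `fat_means` (printed cohort means of SFA, VFA, IMFA and TFA) and
#'   `marginals` (per-variable mean/SD targets used by [cohort_spec()]).
#' @export
reference_cohort <- function() {
  list(
    flow = c(screened = 159L, included = 98L, followup = 61L),
    sex = c(female_survivors = 37L, female_deceased = 14L, n = 98L),
    fat_means = c(SFA = 66.92, VFA = 61.35, IMFA = 5.58, TFA = 133.84),
    marginals = list(
      age        = c(mean = 63.41, sd = 15.80),
      female_p   = 0.5204,
      height_m   = c(mean = 1.66, sd = 0.09),
      bmi        = c(mean = 25.85, sd = 4.65),
      ecog_p     = c(`0` = 0.600, `1` = 0.284, `2` = 0.084, `3` = 0.032),
      grade_p    = c(G1 = 0.474, G2 = 0.333, G3 = 0.141, G4 = 0.052),
      metastasis_p = 0.392,
      albumin    = c(mean = 3.98, sd = 0.61),
      ldh        = c(mean = 206.04, sd = 79.70),
      urea       = c(mean = 37.85, sd = 13.77),
      glucose    = c(mean = 117.37, sd = 30.44),
      fibrinogen = c(mean = 537.37, sd = 155.60),
      composition = rbind(
        data.frame(measure = "body_area", mean = 262.05, sd = 64.24),
        data.frame(measure = "SFA",   mean = 66.59, sd = 33.12),
        data.frame(measure = "VFA",   mean = 61.55, sd = 38.72),
        data.frame(measure = "IMFA",  mean = 5.61,  sd = 3.82),
        data.frame(measure = "VLDM",  mean = 4.88,  sd = 2.73),
        data.frame(measure = "LDMA",  mean = 13.27, sd = 5.29),
        data.frame(measure = "NDMA",  mean = 23.67, sd = 8.02),
        data.frame(measure = "HDMA",  mean = 0.35,  sd = 0.30),
        data.frame(measure = "VHDMA", mean = 0.15,  sd = 0.12)
      ),
      mortality_p = 0.337
    )
  )
}

#' Percentage helper for recruitment-flow arithmetic
#'
#' Fraction expressed as a percentage rounded to reporting precision, as
#' used in cohort flowcharts (e.g. patients included of patients screened).
#'
#' @param count numerator count.
#' @param total denominator count.
#' @param digits decimal places for rounding (default 2).
#' @return Numeric percentage.
#' @examples
#' flow_percent(98, 159)
#' @export
flow_percent <- function(count, total, digits = 2) {
  stopifnot(total > 0, count >= 0)
  round(100 * count / total, digits)
}
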