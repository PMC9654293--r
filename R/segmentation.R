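#' Compute the body mask of a CT slice
#'
#' Thresholds the slice at `hu_threshold` (default -500, separating tissue
#' from air), applies morphological closing, fills interior holes, and keeps
#' the largest 8-connected component — which removes the scanner table, arms
#' and other detached objects.
#'
#' @param slice an [hu_slice()].
#' @param hu_threshold HU above which a pixel is considered tissue.
#' @param closing_radius disc radius (pixels) of the morphological closing.
#' @return Logical matrix, `TRUE` inside the body.
#' @export
compute_body_mask <- function(slice, hu_threshold = -500, closing_radius = 3) {
  stopifnot(inherits(slice, "hu_slice"))
  tissue <- slice$hu > hu_threshold
  if (!any(tissue))
    stop("segmentation failure: no tissue above ", hu_threshold, " HU",
         call. = FALSE)
  closed <- EBImage::closing(tissue * 1, .brush(closing_radius)) > 0
  filled <- EBImage::fillHull(closed * 1) > 0
  lab <- EBImage::bwlabel(filled * 1)
  sizes <- tabulate(as.integer(lab))
  # ties broken by the lowest label, which bwlabel assigns deterministically
  keep <- which.max(sizes)
  mask <- as.matrix(lab) == keep
  if (!any(mask))
    stop("segmentation failure: empty body mask", call. = FALSE)
  mask
}

#' Separate the body into subcutaneous, muscle-wall and visceral compartments
#'
#' The abdominal muscle wall is found as the muscle-HU candidate pixels
#' (total-muscle window, default -29..199 HU) after morphological closing,
#' keeping the connected components adjacent to the body boundary (within
#' `boundary_band_fraction` of the maximum body depth). The visceral region
#' is the interior enclosed by the wall; the subcutaneous region is the
#' remainder of the body. The spatial separation rule is this module's own
#' construction — it is validated against phantoms with known geometry.
#'
#' @param slice an [hu_slice()].
#' @param body logical body mask from [compute_body_mask()].
#' @param bands a [hu_band_table()].
#' @param closing_radius disc radius (pixels) of the closing applied to the
#'   muscle-candidate mask (bridges myosteatotic speckle).
#' @param boundary_band_fraction wall components must reach into the body
#'   rind whose depth is at most this fraction of the maximum body depth.
#' @return An object of class `compartment_masks`: logical matrices `body`,
#'   `subcut_region`, `musclewall_region`, `visceral_region` (pairwise
#'   disjoint, all within the body).
#' @export
separate_compartments <- function(slice, body, bands = hu_band_table(),
                                  closing_radius = 5,
                                  boundary_band_fraction = 0.4) {
  stopifnot(inherits(slice, "hu_slice"), is.logical(body), any(body))
  tma <- attr(bands, "tma")
  candidate <- body & slice$hu >= tma[1] & slice$hu <= tma[2]

  empty <- matrix(FALSE, nrow(body), ncol(body))
  if (!any(candidate)) {
    warning("no muscle-band pixels in body; whole body assigned to the ",
            "subcutaneous region", call. = FALSE)
    return(.compartment_masks(body, subcut = body, wall = empty,
                              visceral = empty))
  }

  closed <- (EBImage::closing(candidate * 1, .brush(closing_radius)) > 0) & body
  depth <- as.matrix(EBImage::distmap(body * 1))
  rind <- body & depth <= boundary_band_fraction * max(depth)

  lab <- EBImage::bwlabel(closed * 1)
  touching <- sort(unique(as.integer(lab)[rind & closed]))
  touching <- touching[touching > 0]
  wall <- matrix(as.integer(lab) %in% touching, nrow(body), ncol(body)) & closed

  if (!any(wall)) {
    warning("no wall component adjacent to the body boundary; whole body ",
            "assigned to the subcutaneous region", call. = FALSE)
    return(.compartment_masks(body, subcut = body, wall = empty,
                              visceral = empty))
  }

  visceral <- (EBImage::fillHull(wall * 1) > 0) & !wall & body
  if (!any(visceral))
    warning("degenerate anatomy: muscle wall encloses no interior; ",
            "visceral areas will be 0", call. = FALSE)
  subcut <- body & !wall & !visceral
  .compartment_masks(body, subcut, wall, visceral)
}

.compartment_masks <- function(body, subcut, wall, visceral) {
  structure(list(body = body, subcut_region = subcut,
                 musclewall_region = wall, visceral_region = visceral),
            class = "compartment_masks")
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat(sprintf("<compartment_masks> body %d px | subcut %d | wall %d | visceral %d\n",
              sum(x$body), sum(x$subcut_region), sum(x$musclewall_region),
              sum(x$visceral_region)))
  invisible(x)
}

#' Area of a HU band within a region
#'
#' Counts region pixels whose HU lies in the inclusive integer window
#' `band = c(low, high)` and converts to cm2 via the pixel area.
#'
#' @param slice an [hu_slice()].
#' @param region logical matrix congruent with the slice (empty region gives 0).
#' @param band inclusive integer HU bounds `c(low, high)`.
#' @return Area in cm2.
#' @examples
#' s <- hu_slice(matrix(50L, 10, 10), c(1, 1))
#' band_area(s, matrix(TRUE, 10, 10), c(35, 100))  # 1 cm2
#' @export
band_area <- function(slice, region, band) {
  stopifnot(inherits(slice, "hu_slice"),
            identical(dim(region), dim(slice$hu)))
  sum(region & slice$hu >= band[1] & slice$hu <= band[2]) *
    pixel_area_cm2(slice)
}

#' Quantify the composition measures of a segmented slice
#'
#' Applies the HU band table within each compartment: the fat window inside
#' the subcutaneous, visceral and muscle-wall regions gives SFA, VFA and
#' IMFA (TFA is their sum); the five muscle windows inside the muscle wall
#' give VLDM/LDMA/NDMA/HDMA/VHDMA, whose union window gives TMA; body_area
#' is the body mask area.
#'
#' @param slice an [hu_slice()].
#' @param masks a `compartment_masks` object.
#' @param bands a [hu_band_table()].
#' @param height_m patient height in meters (optional; enables normalized
#'   areas downstream).
#' @param rater_id measurement-session label.
#' @return An object of class `composition_record`: patient/timepoint/rater
#'   metadata, `area_cm2` (named numeric), `area_norm` (filled by
#'   [normalize_by_height()]), `height_m`.
#' @export
quantify_slice <- function(slice, masks, bands = hu_band_table(),
                           height_m = NA_real_, rater_id = "rater") {
  stopifnot(inherits(slice, "hu_slice"), inherits(masks, "compartment_masks"))
  fat <- unlist(bands[bands$name == "fat", c("hu_low", "hu_high")],
                use.names = FALSE)
  muscle <- bands[bands$name != "fat", ]
  tma <- attr(bands, "tma")

  area <- c(
    SFA  = band_area(slice, masks$subcut_region, fat),
    VFA  = band_area(slice, masks$visceral_region, fat),
    IMFA = band_area(slice, masks$musclewall_region, fat)
  )
  area["TFA"] <- area[["SFA"]] + area[["VFA"]] + area[["IMFA"]]
  for (i in seq_len(nrow(muscle)))
    area[muscle$name[i]] <- band_area(slice, masks$musclewall_region,
                                      c(muscle$hu_low[i], muscle$hu_high[i]))
  area["TMA"] <- band_area(slice, masks$musclewall_region, tma)
  area["body_area"] <- sum(masks$body) * pixel_area_cm2(slice)
  area <- area[composition_measures()]

  composition_record(slice$patient_id, slice$timepoint, rater_id,
                     area_cm2 = area, height_m = height_m,
                     acquisition_date = slice$acquisition_date)
}

#' Construct a composition record
#'
#' @param patient_id,timepoint,rater_id record keys.
#' @param area_cm2 named numeric of areas in cm2.
#' @param area_norm named numeric of height-normalized areas (cm2/m2),
#'   usually filled by [normalize_by_height()].
#' @param height_m patient height in meters.
#' @param acquisition_date slice date (for the follow-up interval rule).
#' @return An object of class `composition_record`.
#' @export
composition_record <- function(patient_id, timepoint, rater_id, area_cm2,
                               area_norm = NULL, height_m = NA_real_,
                               acquisition_date = as.Date(NA)) {
  stopifnot(all(area_cm2 >= 0))
  structure(list(patient_id = patient_id, timepoint = timepoint,
                 rater_id = rater_id, area_cm2 = area_cm2,
                 area_norm = area_norm, height_m = height_m,
                 acquisition_date = acquisition_date),
            class = "composition_record")
}

#' @export
print.composition_record <- function(x, ...) {
  cat(sprintf("<composition_record> patient %s, %s, rater %s\n",
              x$patient_id, x$timepoint, x$rater_id))
  print(round(x$area_cm2, 2))
  invisible(x)
}

#' Segment and quantify a slice in one step
#'
#' Convenience wrapper: body mask, compartment separation, band
#' quantification.
#'
#' @inheritParams quantify_slice
#' @inheritParams compute_body_mask
#' @inheritParams separate_compartments
#' @param body_closing_radius closing radius for the body mask.
#' @return A `composition_record`.
#' @export
measure_slice <- function(slice, bands = hu_band_table(),
                          height_m = NA_real_, rater_id = "rater",
                          hu_threshold = -500, body_closing_radius = 3,
                          closing_radius = 5, boundary_band_fraction = 0.4) {
  body <- compute_body_mask(slice, hu_threshold, body_closing_radius)
  masks <- separate_compartments(slice, body, bands, closing_radius,
                                 boundary_band_fraction)
  quantify_slice(slice, masks, bands, height_m, rater_id)
}
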