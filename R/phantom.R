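#' Specification of a synthetic abdominal CT phantom
#'
#' Defines the geometry and tissue radiodensities of a ring phantom used to
#' validate the segmentation stage: an elliptical body cross-section with,
#' from the outside in, a subcutaneous fat ring, an abdominal muscle wall,
#' and a visceral cavity containing fat and soft-tissue "organ" blobs.
#' Myosteatotic fat speckle can be painted inside the muscle wall. Ground
#' truth for every composition measure is computed from the rasterized
#' masks, so a zero-noise phantom can be recovered exactly.
#'
#' The muscle wall is painted with a discrete-uniform HU spectrum across
#' `muscle_hu_range` so that all five muscle radiodensity bands carry
#' non-zero area and, under additive Gaussian noise, crossings at interior
#' band edges cancel in expectation.
#'
#' Two seeds are carried: `layout_seed` fixes the speckle and organ layout
#' (so the same spec always produces identical masks) while `seed` drives
#' only the additive HU noise field.
#'
#' @param body_axes ellipse semi-axes of the body, mm (row axis, col axis).
#' @param subcut_thickness thickness of the subcutaneous fat ring, mm.
#' @param musclewall_thickness thickness of the muscle wall, mm.
#' @param visceral_fat_fraction target proportion of the visceral cavity
#'   occupied by fat (the remainder is soft-tissue organ blobs).
#' @param tissue_hu_means named HU means for `air`, `subcutaneous_fat`,
#'   `visceral_fat`, `intermuscular_fat` and `organ`.
#' @param muscle_hu_range inclusive integer HU range painted uniformly over
#'   the muscle wall.
#' @param speckle_fraction target fraction of wall pixels painted as
#'   intermuscular fat speckle.
#' @param tissue_hu_sd standard deviation of additive i.i.d. Gaussian HU
#'   noise (0 = noiseless).
#' @param pixel_spacing mm per pixel (row, col).
#' @param grid_shape grid size in pixels (rows, cols).
#' @param organ_depth_fraction organs are only placed where the body depth
#'   (distance to the body boundary) exceeds this fraction of the maximum
#'   depth, keeping them clear of the wall-adjacency band used by
#'   segmentation.
#' @param seed integer seed for the noise field.
#' @param layout_seed integer seed for speckle/organ placement.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_axes = c(120, 95),
                         subcut_thickness = 14,
                         musclewall_thickness = 14,
                         visceral_fat_fraction = 0.55,
                         tissue_hu_means = c(air = -1000,
                                             subcutaneous_fat = -110,
                                             visceral_fat = -110,
                                             intermuscular_fat = -110,
                                             organ = 60),
                         muscle_hu_range = c(-15L, 175L),
                         speckle_fraction = 0.12,
                         tissue_hu_sd = 0,
                         pixel_spacing = c(1, 1),
                         grid_shape = c(256L, 256L),
                         organ_depth_fraction = 0.5,
                         seed = 1L,
                         layout_seed = 1L) {
  spec <- list(body_axes = as.numeric(body_axes),
               subcut_thickness = subcut_thickness,
               musclewall_thickness = musclewall_thickness,
               visceral_fat_fraction = visceral_fat_fraction,
               tissue_hu_means = tissue_hu_means,
               muscle_hu_range = as.integer(muscle_hu_range),
               speckle_fraction = speckle_fraction,
               tissue_hu_sd = tissue_hu_sd,
               pixel_spacing = rep_len(as.numeric(pixel_spacing), 2L),
               grid_shape = rep_len(as.integer(grid_shape), 2L),
               organ_depth_fraction = organ_depth_fraction,
               seed = as.integer(seed),
               layout_seed = as.integer(layout_seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @param spec a `phantom_spec`.
#' @export
validate_phantom_spec <- function(spec) {
  with(spec, {
    if (any(body_axes <= 0)) stop("body_axes must be positive", call. = FALSE)
    if (subcut_thickness <= 0 || musclewall_thickness <= 0)
      stop("ring thicknesses must be > 0", call. = FALSE)
    inner1 <- body_axes - subcut_thickness
    inner2 <- inner1 - musclewall_thickness
    if (any(inner2 <= 0))
      stop("invalid spec: rings exhaust the body ellipse", call. = FALSE)
    if (visceral_fat_fraction < 0 || visceral_fat_fraction > 1)
      stop("visceral_fat_fraction must be in [0, 1]", call. = FALSE)
    if (tissue_hu_sd < 0) stop("tissue_hu_sd must be >= 0", call. = FALSE)
    need <- c("air", "subcutaneous_fat", "visceral_fat",
              "intermuscular_fat", "organ")
    if (!all(need %in% names(tissue_hu_means)))
      stop("tissue_hu_means must name: ", paste(need, collapse = ", "),
           call. = FALSE)
    bands <- hu_band_table()
    fat <- unlist(bands[bands$name == "fat", c("hu_low", "hu_high")])
    for (tt in c("subcutaneous_fat", "visceral_fat", "intermuscular_fat"))
      if (tissue_hu_means[[tt]] < fat[1] || tissue_hu_means[[tt]] > fat[2])
        stop(tt, " mean HU outside the fat window", call. = FALSE)
    if (tissue_hu_means[["air"]] >= -500)
      stop("air mean HU must be below the body threshold", call. = FALSE)
    tma <- attr(bands, "tma")
    if (muscle_hu_range[1] < tma[1] || muscle_hu_range[2] > tma[2])
      stop("muscle_hu_range outside the total muscle window", call. = FALSE)
  })
  invisible(spec)
}

# evaluate expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# pixel-centre ellipse raster; a along columns (x), b along rows (y), in mm
.raster_ellipse <- function(grid_shape, spacing, a, b) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  y <- (seq_len(nr) - (nr + 1) / 2) * spacing[1]
  x <- (seq_len(nc) - (nc + 1) / 2) * spacing[2]
  outer(y^2 / b^2, x^2 / a^2, "+") <= 1
}

.brush <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")

#' Generate a CT phantom with known compartment areas
#'
#' Rasterizes the nested-ellipse geometry of a [phantom_spec()], paints each
#' tissue at its configured HU, adds i.i.d. Gaussian noise, and computes the
#' ground-truth area of every composition measure by exact pixel count times
#' pixel area on the same raster (so downstream recovery can be exact at
#' zero noise).
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom` with elements `slice` (an
#'   [hu_slice()]), `truth` (named cm2 areas for SFA, VFA, IMFA, TFA, VLDM,
#'   LDMA, NDMA, HDMA, VHDMA, TMA and body_area), and `masks` (the
#'   generating boolean masks: body, subcut, wall, cavity, speckle, organ).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  gs <- spec$grid_shape; sp <- spec$pixel_spacing
  ax <- spec$body_axes
  body   <- .raster_ellipse(gs, sp, ax[2], ax[1])
  sub_in <- .raster_ellipse(gs, sp, ax[2] - spec$subcut_thickness,
                            ax[1] - spec$subcut_thickness)
  wal_in <- .raster_ellipse(gs, sp,
                            ax[2] - spec$subcut_thickness - spec$musclewall_thickness,
                            ax[1] - spec$subcut_thickness - spec$musclewall_thickness)
  subcut <- body & !sub_in
  wall   <- sub_in & !wal_in
  cavity <- wal_in
  if (!any(subcut) || !any(wall) || !any(cavity))
    stop("invalid spec: a compartment ring rasterizes to zero pixels",
         call. = FALSE)

  layout <- .with_seed(spec$layout_seed, {
    speckle <- .place_speckle(wall, spec$speckle_fraction, sp)
    organ <- .place_organs(body, cavity, 1 - spec$visceral_fat_fraction,
                           spec$organ_depth_fraction, sp)
    muscle_px <- which(wall & !speckle)
    # balanced spectrum: every HU value equally represented (up to one
    # pixel), then shuffled — band truths are then exact multiples and the
    # realized density near band edges does not fluctuate between layouts
    spectrum <- seq(spec$muscle_hu_range[1], spec$muscle_hu_range[2])
    muscle_hu <- sample(rep(spectrum, length.out = length(muscle_px)))
    list(speckle = speckle, organ = organ,
         muscle_px = muscle_px, muscle_hu = muscle_hu)
  })

  hu0 <- matrix(spec$tissue_hu_means[["air"]], gs[1], gs[2])
  hu0[subcut] <- spec$tissue_hu_means[["subcutaneous_fat"]]
  hu0[cavity] <- spec$tissue_hu_means[["visceral_fat"]]
  hu0[layout$organ] <- spec$tissue_hu_means[["organ"]]
  hu0[layout$muscle_px] <- layout$muscle_hu
  hu0[layout$speckle] <- spec$tissue_hu_means[["intermuscular_fat"]]

  hu <- if (spec$tissue_hu_sd > 0) {
    .with_seed(spec$seed,
               hu0 + matrix(stats::rnorm(length(hu0), 0, spec$tissue_hu_sd),
                            gs[1], gs[2]))
  } else hu0
  hu <- pmin(pmax(.round_half_away(hu), -1024), 3071)

  slice <- hu_slice(hu, sp, patient_id = "phantom", timepoint = "diagnosis")
  px <- pixel_area_cm2(slice)

  bands <- hu_band_table()
  muscle_bands <- bands[bands$name != "fat", ]
  band_counts <- vapply(seq_len(nrow(muscle_bands)), function(i) {
    sum(layout$muscle_hu >= muscle_bands$hu_low[i] &
        layout$muscle_hu <= muscle_bands$hu_high[i])
  }, numeric(1))
  names(band_counts) <- muscle_bands$name

  truth <- c(
    SFA  = sum(subcut) * px,
    VFA  = sum(cavity & !layout$organ) * px,
    IMFA = sum(layout$speckle) * px,
    band_counts * px,
    body_area = sum(body) * px
  )
  truth["TFA"] <- truth["SFA"] + truth["VFA"] + truth["IMFA"]
  truth["TMA"] <- sum(band_counts) * px
  truth <- truth[composition_measures()]

  structure(list(slice = slice, truth = truth,
                 masks = list(body = body, subcut = subcut, wall = wall,
                              cavity = cavity, speckle = layout$speckle,
                              organ = layout$organ),
                 spec = spec),
            class = "phantom")
}

# myosteatotic speckle: small fat blobs seeded in the eroded wall interior
# (clearance keeps holes away from the wall boundary so morphological
# closing restores the wall exactly at zero noise)
.place_speckle <- function(wall, fraction, spacing) {
  speckle <- matrix(FALSE, nrow(wall), ncol(wall))
  if (fraction <= 0) return(speckle)
  interior <- EBImage::erode(wall * 1, .brush(3)) > 0
  cand <- which(interior)
  if (length(cand) == 0L) return(speckle)
  blob_px <- 5  # plus-shaped blob from a radius-1 disc brush
  n_seed <- max(1L, round(fraction * sum(wall) / blob_px))
  seeds <- .poisson_disc(cand, nrow(wall), min_dist = 6,
                         n_target = n_seed)
  speckle[seeds] <- TRUE
  speckle <- EBImage::dilate(speckle * 1, .brush(1)) > 0
  speckle & interior
}

# soft-tissue organ blobs in the central cavity, clear of the muscle wall
.place_organs <- function(body, cavity, target_fraction, depth_fraction,
                          spacing) {
  organ <- matrix(FALSE, nrow(body), ncol(body))
  if (target_fraction <= 0) return(organ)
  depth <- EBImage::distmap(body * 1)
  core <- cavity & (as.matrix(depth) > depth_fraction * max(depth))
  # clearance beyond the closing diameter: organs must never be bridged
  # into the wall by the segmentation's morphological closing
  core <- core & (EBImage::erode(cavity * 1, .brush(12)) > 0)
  cand <- which(core)
  if (length(cand) == 0L) return(organ)
  nr <- nrow(body)
  target_px <- target_fraction * sum(cavity)
  for (i in seq_len(400)) {
    if (sum(organ) >= target_px) break
    centre <- cand[sample.int(length(cand), 1L)]
    r <- stats::runif(1, 5, 11)
    ci <- (centre - 1L) %% nr + 1L
    cj <- (centre - 1L) %/% nr + 1L
    ii <- pmax(1L, ci - ceiling(r)):pmin(nr, ci + ceiling(r))
    jj <- pmax(1L, cj - ceiling(r)):pmin(ncol(body), cj + ceiling(r))
    disc <- outer((ii - ci)^2, (jj - cj)^2, "+") <= r^2
    sub <- organ[ii, jj]
    sub[disc & core[ii, jj]] <- TRUE
    organ[ii, jj] <- sub
  }
  organ
}

# greedy Poisson-disc thinning of candidate pixel indices
.poisson_disc <- function(cand, nr, min_dist, n_target) {
  pool <- sample(cand)
  kept_i <- kept_j <- numeric(0)
  kept <- integer(0)
  for (p in pool) {
    if (length(kept) >= n_target) break
    pi <- (p - 1L) %% nr + 1L
    pj <- (p - 1L) %/% nr + 1L
    if (length(kept) == 0L ||
        all((kept_i - pi)^2 + (kept_j - pj)^2 >= min_dist^2)) {
      kept <- c(kept, p)
      kept_i <- c(kept_i, pi); kept_j <- c(kept_j, pj)
    }
  }
  kept
}
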