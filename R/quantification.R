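#' Normalize composition areas by squared height
#'
#' Divides every area (cm2) by the square of the patient's height in meters,
#' giving the height-normalized indices (cm2/m2) used in cohort analyses.
#' Works on a single `composition_record` or on a long measurement
#' data.frame (columns `patient_id`, `measure`, `area_cm2`) with a patient
#' table supplying `height_m`.
#'
#' @param x a `composition_record` or a long measurement data.frame.
#' @param ... passed to methods.
#' @return Same shape as the input with normalized values filled in
#'   (`area_norm` element or column).
#' @export
normalize_by_height <- function(x, ...) UseMethod("normalize_by_height")

#' @rdname normalize_by_height
#' @export
normalize_by_height.composition_record <- function(x, ...) {
  h <- x$height_m
  if (is.na(h) || h <= 0.5 || h >= 2.5)
    stop("height must be in (0.5, 2.5) m to normalize; record flagged",
         call. = FALSE)
  x$area_norm <- x$area_cm2 / h^2
  x
}

#' @rdname normalize_by_height
#' @param patients data.frame with `patient_id` and `height_m`.
#' @export
normalize_by_height.data.frame <- function(x, patients, ...) {
  stopifnot(all(c("patient_id", "measure", "area_cm2") %in% names(x)),
            all(c("patient_id", "height_m") %in% names(patients)))
  h <- patients$height_m[match(x$patient_id, patients$patient_id)]
  bad <- is.na(h) | h <= 0.5 | h >= 2.5
  x$area_norm <- ifelse(bad, NA_real_, x$area_cm2 / h^2)
  if (any(bad))
    warning(sum(bad), " measurement rows lack a usable height and were ",
            "left unnormalized", call. = FALSE)
  x
}

#' Pair duplicate-rater measurements per measure
#'
#' Reshapes a long measurement table (two raters) into per-measure paired
#' value lists, the input of [reliability_gate()].
#'
#' @param measures long data.frame with `patient_id`, `timepoint`, `rater`,
#'   `measure` and a value column.
#' @param value column to pair (default `area_norm`, falling back to
#'   `area_cm2`).
#' @param raters the two rater labels to pair.
#' @return data.frame with columns `measure`, `patient_id`, `timepoint`,
#'   `value_a`, `value_b`.
#' @export
make_rater_pairs <- function(measures, value = NULL, raters = NULL) {
  if (is.null(value))
    value <- if ("area_norm" %in% names(measures)) "area_norm" else "area_cm2"
  if (is.null(raters)) {
    raters <- sort(unique(measures$rater))
    if (length(raters) != 2L)
      stop("expected exactly two raters, found: ",
           paste(raters, collapse = ", "), call. = FALSE)
  }
  a <- measures[measures$rater == raters[1],
                c("measure", "patient_id", "timepoint", value)]
  b <- measures[measures$rater == raters[2],
                c("measure", "patient_id", "timepoint", value)]
  names(a)[4] <- "value_a"; names(b)[4] <- "value_b"
  pairs <- merge(a, b, by = c("measure", "patient_id", "timepoint"))
  dup <- duplicated(pairs[, c("measure", "patient_id", "timepoint")])
  if (any(dup))
    stop("duplicated (patient, timepoint, rater) measurement keys",
         call. = FALSE)
  pairs[order(pairs$measure, pairs$patient_id, pairs$timepoint), ]
}

#' Reliability gate on duplicate-rater measurements
#'
#' Computes Spearman's rho between the two raters for every measure and
#' retains a measure only when rho is strictly greater than the threshold.
#' Dropped measures are excluded from all downstream analyses. Constant
#' value lists have undefined rho and are dropped with an explicit reason.
#'
#' @param pairs output of [make_rater_pairs()].
#' @param threshold retention threshold on Spearman's rho (strict).
#' @return data.frame report: `measure`, `rho`, `n`, `retained`, `reason`.
#' @export
reliability_gate <- function(pairs, threshold = 0.85) {
  out <- lapply(split(pairs, pairs$measure), function(p) {
    ok <- stats::complete.cases(p$value_a, p$value_b)
    n <- sum(ok)
    if (n < 3)
      return(data.frame(measure = p$measure[1], rho = NA_real_, n = n,
                        retained = FALSE,
                        reason = "fewer than 3 paired observations"))
    if (stats::sd(p$value_a[ok]) == 0 || stats::sd(p$value_b[ok]) == 0)
      return(data.frame(measure = p$measure[1], rho = NA_real_, n = n,
                        retained = FALSE,
                        reason = "constant values; rho undefined"))
    rho <- stats::cor(p$value_a[ok], p$value_b[ok], method = "spearman")
    data.frame(measure = p$measure[1], rho = rho, n = n,
               retained = rho > threshold,
               reason = if (rho > threshold) "" else
                 sprintf("rho %.3f <= %.2f", rho, threshold))
  })
  report <- do.call(rbind, out)
  rownames(report) <- NULL
  attr(report, "threshold") <- threshold
  report
}

#' Average duplicate-rater records
#'
#' Arithmetic mean of the two raters' values per measure; the resulting
#' record carries `rater_id = "mean"`.
#'
#' @param record_a,record_b `composition_record`s of the same patient,
#'   timepoint and height.
#' @return A `composition_record`.
#' @export
average_raters <- function(record_a, record_b) {
  stopifnot(inherits(record_a, "composition_record"),
            inherits(record_b, "composition_record"),
            identical(record_a$patient_id, record_b$patient_id),
            identical(record_a$timepoint, record_b$timepoint))
  m <- intersect(names(record_a$area_cm2), names(record_b$area_cm2))
  rec <- composition_record(
    record_a$patient_id, record_a$timepoint, "mean",
    area_cm2 = (record_a$area_cm2[m] + record_b$area_cm2[m]) / 2,
    height_m = record_a$height_m,
    acquisition_date = record_a$acquisition_date)
  if (!is.null(record_a$area_norm) && !is.null(record_b$area_norm))
    rec$area_norm <- (record_a$area_norm[m] + record_b$area_norm[m]) / 2
  rec
}

#' Follow-up change between two composition records
#'
#' Final minus initial value per measure (gain positive), provided the
#' interval between acquisitions is at least `min_interval_days` (default
#' 365: a follow-up study must be at least one year after diagnosis).
#'
#' @param initial,final normalized, rater-averaged `composition_record`s of
#'   the same patient.
#' @param min_interval_days minimum acquisition interval in days.
#' @return A list of class `delta_record` with `patient_id`, `delta` (named
#'   numeric, cm2/m2), `interval_years` and `excluded`/`reason` fields;
#'   excluded records carry no deltas.
#' @export
compute_delta <- function(initial, final, min_interval_days = 365) {
  stopifnot(inherits(initial, "composition_record"),
            inherits(final, "composition_record"),
            identical(initial$patient_id, final$patient_id))
  if (is.null(initial$area_norm) || is.null(final$area_norm))
    stop("records must be normalized before computing deltas", call. = FALSE)
  interval <- as.numeric(final$acquisition_date - initial$acquisition_date)
  if (is.na(interval))
    stop("both records need acquisition dates", call. = FALSE)
  if (interval < 0)
    stop("chronology error: final record precedes initial record",
         call. = FALSE)
  if (interval < min_interval_days)
    return(structure(list(patient_id = initial$patient_id, delta = NULL,
                          interval_years = interval / 365.25,
                          excluded = TRUE,
                          reason = sprintf("interval %.2f y < %.2f y",
                                           interval / 365.25,
                                           min_interval_days / 365.25)),
                     class = "delta_record"))
  m <- intersect(names(initial$area_norm), names(final$area_norm))
  structure(list(patient_id = initial$patient_id,
                 delta = final$area_norm[m] - initial$area_norm[m],
                 interval_years = interval / 365.25,
                 excluded = FALSE, reason = ""),
            class = "delta_record")
}

#' Drop variables with excessive missingness
#'
#' Removes variables whose missing fraction is strictly greater than
#' `max_missing` (default 0.40) and reports them. Patients are never
#' removed by this filter.
#'
#' @param table a data.frame.
#' @param max_missing maximum tolerated missing fraction (strict).
#' @param protect column names never dropped (identifiers, outcomes).
#' @return list with `table` (filtered) and `dropped` (data.frame:
#'   `variable`, `missing_fraction`).
#' @export
missingness_filter <- function(table, max_missing = 0.40,
                               protect = c("patient_id", "deceased",
                                           "death_cause")) {
  frac <- vapply(table, function(col) mean(is.na(col)), numeric(1))
  drop <- names(frac)[frac > max_missing & !names(frac) %in% protect]
  list(table = table[, !names(table) %in% drop, drop = FALSE],
       dropped = data.frame(variable = drop,
                            missing_fraction = unname(frac[drop])))
}

#' Quantify a simulated or measured cohort
#'
#' The measurement-processing chain applied to a duplicate-rater long
#' measurement table: normalize by squared height, gate measures by
#' inter-rater Spearman reliability, average the raters, and compute
#' follow-up changes for patients whose second CT is at least one year
#' after diagnosis.
#'
#' @param measures long data.frame (`patient_id`, `timepoint`, `rater`,
#'   `measure`, `area_cm2`).
#' @param patients patient table with `patient_id`, `height_m`,
#'   `diagnosis_date`, `followup_date`.
#' @param gate_threshold Spearman retention threshold.
#' @param min_interval_days minimum follow-up interval.
#' @return list of class `quantified_cohort`: `baseline` (wide data.frame of
#'   rater-averaged normalized diagnosis measures), `delta` (wide
#'   data.frame of follow-up changes, `delta_` prefix), `gate` (reliability
#'   report), `excluded` (per-patient delta exclusions with reasons).
#' @export
quantify_cohort <- function(measures, patients, gate_threshold = 0.85,
                            min_interval_days = 365) {
  norm <- normalize_by_height(measures, patients)
  gate <- reliability_gate(make_rater_pairs(norm), gate_threshold)
  retained <- gate$measure[gate$retained]
  norm <- norm[norm$measure %in% retained, ]

  avg <- stats::aggregate(area_norm ~ patient_id + timepoint + measure,
                          data = norm, FUN = mean)

  wide <- function(tp) {
    sub <- avg[avg$timepoint == tp, ]
    if (!nrow(sub)) return(NULL)
    stats::reshape(sub[, c("patient_id", "measure", "area_norm")],
                   idvar = "patient_id", timevar = "measure",
                   direction = "wide")
  }
  base <- wide("diagnosis")
  names(base) <- sub("^area_norm\\.", "", names(base))
  fup <- wide("followup")

  delta <- NULL
  excluded <- data.frame(patient_id = character(), reason = character())
  if (!is.null(fup)) {
    names(fup) <- sub("^area_norm\\.", "", names(fup))
    common <- intersect(base$patient_id, fup$patient_id)
    interval <- as.numeric(
      patients$followup_date[match(common, patients$patient_id)] -
        patients$diagnosis_date[match(common, patients$patient_id)])
    keep <- !is.na(interval) & interval >= min_interval_days
    if (any(!keep))
      excluded <- data.frame(
        patient_id = common[!keep],
        reason = sprintf("interval %.2f y < %.2f y",
                         interval[!keep] / 365.25,
                         min_interval_days / 365.25))
    common <- common[keep]
    if (length(common)) {
      mcols <- setdiff(names(base), "patient_id")
      d <- fup[match(common, fup$patient_id), mcols, drop = FALSE] -
        base[match(common, base$patient_id), mcols, drop = FALSE]
      names(d) <- paste0("delta_", mcols)
      delta <- cbind(data.frame(patient_id = common,
                                interval_years = interval[keep] / 365.25),
                     d)
      rownames(delta) <- NULL
    }
  }
  no_fup <- setdiff(base$patient_id,
                    if (is.null(fup)) character() else fup$patient_id)
  if (length(no_fup))
    excluded <- rbind(excluded,
                      data.frame(patient_id = no_fup,
                                 reason = "no follow-up CT"))
  structure(list(baseline = base, delta = delta, gate = gate,
                 excluded = excluded),
            class = "quantified_cohort")
}
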