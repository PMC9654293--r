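#' Write a cohort to CSV files
#'
#' Writes `patients.csv` (one row per patient; ISO-8601 dates, empty string
#' as the missing marker) and `measures.csv` (long form: one row per
#' patient, timepoint, rater and measure) under `dir`. A wide convenience
#' export `measures_wide.csv` (one row per patient-timepoint-rater, one
#' column per measure) is written alongside. Unknown columns are preserved.
#'
#' @param cohort a `cohort` from [generate_cohort()], or any list with
#'   `patients` and `measures` data.frames.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$measures, file.path(dir, "measures.csv"),
                   row.names = FALSE, na = "")
  wide <- stats::reshape(cohort$measures, idvar = c("patient_id",
                                                    "timepoint", "rater"),
                         timevar = "measure", direction = "wide")
  names(wide) <- sub("^area_cm2\\.", "", names(wide))
  utils::write.csv(wide, file.path(dir, "measures_wide.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}

#' Read a cohort from CSV files
#'
#' Reads the `patients.csv`/`measures.csv` pair written by [write_cohort()]
#' back into typed columns (dates as `Date`, numerics as numeric, empty
#' strings as missing). Duplicated (patient, timepoint, rater, measure)
#' measurement keys are an integrity error.
#'
#' @param dir directory containing the two files.
#' @return list with `patients` and `measures` data.frames.
#' @export
read_cohort <- function(dir) {
  pfile <- file.path(dir, "patients.csv")
  mfile <- file.path(dir, "measures.csv")
  if (!file.exists(pfile) || !file.exists(mfile))
    stop("cohort directory must contain patients.csv and measures.csv",
         call. = FALSE)
  patients <- utils::read.csv(pfile, na.strings = "",
                              stringsAsFactors = FALSE)
  for (col in c("diagnosis_date", "followup_date"))
    if (col %in% names(patients))
      patients[[col]] <- .parse_iso_date(patients[[col]])
  if ("has_followup" %in% names(patients))
    patients$has_followup <- as.logical(patients$has_followup)
  measures <- utils::read.csv(mfile, na.strings = "",
                              stringsAsFactors = FALSE)
  key <- measures[, c("patient_id", "timepoint", "rater", "measure")]
  if (anyDuplicated(key))
    stop("integrity error: duplicated (patient, timepoint, rater, measure) ",
         "keys in measures.csv", call. = FALSE)
  list(patients = patients, measures = measures)
}

#' Write composition records to CSV
#'
#' Long form: one row per (patient, timepoint, rater, measure), with raw
#' and normalized areas when available.
#'
#' @param records list of `composition_record`s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measures <- function(records, path) {
  rows <- lapply(records, function(r) {
    data.frame(patient_id = r$patient_id, timepoint = r$timepoint,
               rater = r$rater_id, measure = names(r$area_cm2),
               area_cm2 = unname(r$area_cm2),
               area_norm = if (is.null(r$area_norm)) NA_real_
                           else unname(r$area_norm[names(r$area_cm2)]),
               height_m = r$height_m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  key <- out[, c("patient_id", "timepoint", "rater", "measure")]
  if (anyDuplicated(key))
    stop("integrity error: duplicated (patient, timepoint, rater) records",
         call. = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
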