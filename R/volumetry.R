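# Ellipsoid volumetry: tri-planar diameters -> lesion volumes.

#' Ellipsoid volume from three orthogonal diameters
#'
#' Approximates a lesion as an ellipsoid whose three principal diameters are
#' the maximal diameters measured in the transverse, coronal and sagittal
#' planes. With semi-axes `a = d1/2`, `b = d2/2`, `c = d3/2`, the volume is
#' \deqn{V = \frac{4}{3}\pi a b c = \frac{\pi}{6} d_1 d_2 d_3.}
#' The result is symmetric in the three diameters.
#'
#' @param d1,d2,d3 Diameters in mm; strictly positive and finite. Vectors are
#'   recycled to a common length.
#' @return Volume(s) in mm^3.
#' @examples
#' ellipsoid_volume(10, 10, 10)  # sphere: (pi/6) * 1000
#' ellipsoid_volume(20, 30, 40)
#' @export
ellipsoid_volume <- function(d1, d2, d3) {
  .check_diameter(d1, "d1")
  .check_diameter(d2, "d2")
  .check_diameter(d3, "d3")
  (pi / 6) * d1 * d2 * d3
}

.check_diameter <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop("diameter '", name, "' must be numeric", call. = FALSE)
  }
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    stop("diameter '", name, "' must be strictly positive and finite; ",
         "offending value(s): ", paste(x[bad][seq_len(min(5, sum(bad)))],
                                       collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Convert a lesion-scan table to per-scan ellipsoid volumes
#'
#' One input row is one lesion measurement at one scan date: the mesenteric
#' metastasis (or the whole conglomerate, measured as a single entity) for one
#' patient. Duplicate `(patient_id, scan_date)` keys are rejected.
#'
#' @param scans data.frame with columns `patient_id`, `scan_date` (Date or
#'   ISO-8601 string), `d_transverse_mm`, `d_coronal_mm`, `d_sagittal_mm`, and
#'   optionally `is_conglomerate` (logical or 0/1; carried through, does not
#'   change the computation).
#' @return data.frame with columns `patient_id`, `scan_date` (Date),
#'   `volume_mm3`, one row per input scan, input order preserved.
#' @export
scans_to_volumes <- function(scans) {
  stopifnot(is.data.frame(scans))
  req <- c("patient_id", "scan_date",
           "d_transverse_mm", "d_coronal_mm", "d_sagittal_mm")
  missing_cols <- setdiff(req, names(scans))
  if (length(missing_cols)) {
    stop("lesion table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(scans) == 0L) {
    return(data.frame(patient_id = character(0),
                      scan_date = as.Date(character(0)),
                      volume_mm3 = numeric(0),
                      stringsAsFactors = FALSE))
  }
  dates <- parse_iso_date(scans$scan_date, field = "scan_date")
  key <- paste(scans$patient_id, format(dates, "%Y-%m-%d"), sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    stop("duplicate (patient_id, scan_date) key(s): ",
         paste(gsub("\r", " @ ", dup), collapse = "; "), call. = FALSE)
  }
  vol <- ellipsoid_volume(scans$d_transverse_mm,
                          scans$d_coronal_mm,
                          scans$d_sagittal_mm)
  data.frame(patient_id = as.character(scans$patient_id),
             scan_date = dates,
             volume_mm3 = vol,
             stringsAsFactors = FALSE)
}

#' Parse strictly ISO-8601 (YYYY-MM-DD) dates
#'
#' @param x Date vector or character vector of ISO dates.
#' @param field Field name used in error messages.
#' @return Date vector.
#' @keywords internal
parse_iso_date <- function(x, field = "date") {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- as.Date(rep(NA_character_, length(x)))
  d[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  bad <- which(!ok | is.na(d))
  if (length(bad)) {
    stop("field '", field, "' contains unparseable ISO-8601 date(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": ",
         paste(utils::head(x[bad], 5), collapse = ", "), call. = FALSE)
  }
  d
}
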