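# CSV I/O and input validation. Schemas:
#   lesion table : patient_id, scan_date (ISO-8601), d_transverse_mm,
#                  d_coronal_mm, d_sagittal_mm, is_conglomerate (0/1, optional)
#   patient table: patient_id, age, sex, symptomatic_at_dx, grade, ki67,
#                  u5hiaa, carcinoid_heart, liver_mets, peritoneal_mets,
#                  extraabdominal_mets, prrt_treated, mlnm_level,
#                  t_symptom_surgery_months, symptom_surgery_event,
#                  t_death_months, death_event
# Booleans are 0/1; an empty cell is missing; decimal point "."; comma
# delimiter; header row required.

LESION_COLS <- c("patient_id", "scan_date", "d_transverse_mm",
                 "d_coronal_mm", "d_sagittal_mm")
PATIENT_COLS <- c("patient_id", "age", "sex", "symptomatic_at_dx", "grade",
                  "ki67", "u5hiaa", "carcinoid_heart", "liver_mets",
                  "peritoneal_mets", "extraabdominal_mets", "prrt_treated",
                  "mlnm_level", "t_symptom_surgery_months",
                  "symptom_surgery_event", "t_death_months", "death_event")
PATIENT_BOOL_COLS <- c("symptomatic_at_dx", "carcinoid_heart", "liver_mets",
                       "peritoneal_mets", "extraabdominal_mets",
                       "prrt_treated", "symptom_surgery_event", "death_event")

#' Read a lesion-measurement CSV
#'
#' @param path Path to a CSV in the lesion-table schema.
#' @return data.frame with parsed dates and a logical `is_conglomerate`.
#' @export
read_lesion_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(LESION_COLS, names(x))
  if (length(missing_cols)) {
    stop("lesion CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(x$is_conglomerate)) x$is_conglomerate <- 0L
  x$patient_id <- as.character(x$patient_id)
  x$scan_date <- parse_iso_date(x$scan_date, "scan_date")
  x$is_conglomerate <- as.logical(as.integer(x$is_conglomerate))
  x
}

#' Read a patient CSV
#'
#' Booleans are read from 0/1, empty cells become `NA`.
#'
#' @param path Path to a CSV in the patient-table schema.
#' @return data.frame with logical flag columns.
#' @export
read_patient_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  missing_cols <- setdiff(PATIENT_COLS, names(x))
  if (length(missing_cols)) {
    stop("patient CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$patient_id <- as.character(x$patient_id)
  for (col in PATIENT_BOOL_COLS) x[[col]] <- as.logical(as.integer(x[[col]]))
  x
}

#' Write a table as CSV (deterministic formatting)
#'
#' Logical columns are written as 0/1, `NA` as an empty cell; no row names.
#'
#' @param x data.frame.
#' @param path Output path.
#' @export
write_table_csv <- function(x, path) {
  for (col in names(x)) {
    if (is.logical(x[[col]])) x[[col]] <- as.integer(x[[col]])
  }
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a lesion table and a patient table together
#'
#' Collects row-level problems (bad dates, non-positive diameters, unknown
#' categories, duplicate keys, negative times, cross-reference gaps) into a
#' single report instead of failing on the first.
#'
#' @param lesions Lesion table (data.frame, as read by [read_lesion_csv()]
#'   or with raw character dates).
#' @param patients Patient table.
#' @return List with `issues` (data.frame: `severity`, `table`, `row`,
#'   `field`, `message`) and `ok` (`TRUE` when no error-severity issues).
#' @export
validate_inputs <- function(lesions, patients) {
  issues <- list()
  add <- function(severity, table, row, field, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, table = table, row = row, field = field,
      message = message, stringsAsFactors = FALSE)
  }

  for (col in setdiff(LESION_COLS, names(lesions))) {
    add("error", "lesions", NA_integer_, col, "required column missing")
  }
  for (col in setdiff(PATIENT_COLS, names(patients))) {
    add("error", "patients", NA_integer_, col, "required column missing")
  }
  if (length(issues)) {
    return(list(issues = do.call(rbind, issues), ok = FALSE))
  }

  dates <- lesions$scan_date
  if (!inherits(dates, "Date")) {
    ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", as.character(dates)) &
      !is.na(suppressWarnings(as.Date(as.character(dates), "%Y-%m-%d")))
    for (i in which(!ok)) {
      add("error", "lesions", i, "scan_date",
          paste0("unparseable ISO-8601 date: '", dates[i], "'"))
    }
    dates <- suppressWarnings(as.Date(as.character(dates), "%Y-%m-%d"))
  }
  for (col in c("d_transverse_mm", "d_coronal_mm", "d_sagittal_mm")) {
    v <- suppressWarnings(as.numeric(lesions[[col]]))
    for (i in which(!is.finite(v) | v <= 0)) {
      add("error", "lesions", i, col,
          paste0("diameter must be strictly positive; got '",
                 lesions[[col]][i], "'"))
    }
  }
  key <- paste(lesions$patient_id, format(dates, "%Y-%m-%d"))
  for (i in which(duplicated(key))) {
    add("error", "lesions", i, "patient_id/scan_date",
        paste0("duplicate key: ", key[i]))
  }

  for (col in c("t_symptom_surgery_months", "t_death_months")) {
    v <- suppressWarnings(as.numeric(patients[[col]]))
    for (i in which(!is.na(v) & v < 0)) {
      add("error", "patients", i, col, "time must be non-negative")
    }
  }
  g <- patients$grade
  for (i in which(!is.na(g) & !(g %in% c(1, 2, 3)))) {
    add("error", "patients", i, "grade",
        paste0("grade must be 1, 2 or 3; got '", g[i], "'"))
  }
  lev <- as.character(patients$mlnm_level)
  for (i in which(!is.na(lev) & !(lev %in% MLNM_LEVELS))) {
    add("error", "patients", i, "mlnm_level",
        paste0("unknown level '", lev[i], "'; expected one of ",
               paste(MLNM_LEVELS, collapse = ", ")))
  }
  sx <- as.character(patients$sex)
  for (i in which(!is.na(sx) & !(sx %in% c("female", "male")))) {
    add("error", "patients", i, "sex",
        paste0("sex must be 'female' or 'male'; got '", sx[i], "'"))
  }
  for (i in which(duplicated(patients$patient_id))) {
    add("error", "patients", i, "patient_id",
        paste0("duplicate patient_id: ", patients$patient_id[i]))
  }

  orphan <- setdiff(unique(lesions$patient_id), patients$patient_id)
  for (p in orphan) {
    add("warning", "lesions", NA_integer_, "patient_id",
        paste0("patient '", p, "' in lesion table absent from patient table"))
  }

  issues_df <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(0), table = character(0),
               row = integer(0), field = character(0),
               message = character(0), stringsAsFactors = FALSE)
  list(issues = issues_df, ok = !any(issues_df$severity == "error"))
}
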