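# Exponential growth kinetics: growth constant g, TGR, progression flag.

#' Exponential growth constant from paired volumes
#'
#' Under a roughly exponential growth model `V2 = V1 * exp(g * t)`, the unique
#' growth constant is `g = log(V2 / V1) / t` (natural log), in units of
#' per month when `t` is in months. Working in volumes is equivalent to the
#' diameter form `3 * log(D2 / D1) / t` because `V` scales as `D^3`.
#'
#' @param v1,v2 Baseline and follow-up volumes (mm^3), strictly positive.
#' @param t Interval in months, strictly positive.
#' @return Growth constant per month (vectorised).
#' @examples
#' growth_constant(1000, 2000, 1)  # log(2): doubling in one month
#' @export
growth_constant <- function(v1, v2, t) {
  for (nm in c("v1", "v2")) {
    v <- get(nm)
    if (!is.numeric(v) || any(!is.finite(v) | v <= 0)) {
      stop("volume '", nm, "' must be strictly positive and finite",
           call. = FALSE)
    }
  }
  if (!is.numeric(t) || any(!is.finite(t) | t <= 0)) {
    stop("interval 't' must be strictly positive and finite (months)",
         call. = FALSE)
  }
  log(v2 / v1) / t
}

#' Tumor growth rate (percent volume change per month)
#'
#' Back-transforms the monthly growth constant to a percentage:
#' `TGR = 100 * (exp(g) - 1)`. Strictly increasing in `g` and bounded below
#' by -100; `g = log(1 + TGR/100)` recovers the constant.
#'
#' @param g Growth constant per month, finite.
#' @return TGR in percent per month.
#' @examples
#' tumor_growth_rate(log(2))  # monthly doubling = +100 %/month
#' @export
tumor_growth_rate <- function(g) {
  if (!is.numeric(g) || any(!is.finite(g))) {
    stop("growth constant 'g' must be finite", call. = FALSE)
  }
  100 * (exp(g) - 1)
}

#' Calendar interval in months
#'
#' Months are defined as 30.4375 days (365.25 / 12); the interval is the day
#' count between the dates divided by that constant.
#'
#' @param date1,date2 Dates (Date or ISO-8601 strings), `date2 >= date1`.
#' @return Interval in months (vectorised).
#' @export
months_between <- function(date1, date2) {
  d1 <- parse_iso_date(date1, "date1")
  d2 <- parse_iso_date(date2, "date2")
  if (any(d2 < d1)) {
    stop("date2 precedes date1 for ", sum(d2 < d1), " pair(s)", call. = FALSE)
  }
  as.numeric(d2 - d1) / 30.4375
}

#' Per-patient growth estimates from serial volumes
#'
#' For each patient the earliest scan is the baseline (V1) and the latest the
#' most recent follow-up (V2); intermediate scans are ignored. Patients with
#' fewer than two distinct scan dates are skipped with a warning; patients
#' whose baseline-to-last interval is below `min_interval_months` are excluded
#' and reported in the `exclusions` attribute.
#'
#' @param volumes data.frame from [scans_to_volumes()]: `patient_id`,
#'   `scan_date`, `volume_mm3`.
#' @param min_interval_months Minimum qualifying interval (default 2 months).
#' @return data.frame, one row per retained patient, with columns
#'   `patient_id`, `v1_mm3`, `v2_mm3`, `interval_months`, `delta_v_mm3`,
#'   `g_per_month`, `tgr_pct_per_month`, `progressed`. Attribute `exclusions`
#'   is a data.frame (`patient_id`, `reason`) listing skipped patients.
#' @export
estimate_growth <- function(volumes, min_interval_months = 2) {
  stopifnot(is.data.frame(volumes),
            all(c("patient_id", "scan_date", "volume_mm3") %in% names(volumes)))
  pid_f <- factor(as.character(volumes$patient_id),
                  levels = unique(as.character(volumes$patient_id)))
  by_pat <- split(seq_len(nrow(volumes)), pid_f)

  first_i <- last_i <- integer(0)
  excl_id <- excl_reason <- character(0)
  for (pid in names(by_pat)) {
    idx <- by_pat[[pid]]
    dts <- volumes$scan_date[idx]
    if (length(unique(dts)) < 2L) {
      warning("patient '", pid, "' has fewer than two distinct scan dates; ",
              "skipped", call. = FALSE)
      excl_id <- c(excl_id, pid)
      excl_reason <- c(excl_reason, "fewer than two scans")
      next
    }
    i1 <- idx[which.min(dts)]
    i2 <- idx[which.max(dts)]
    t <- months_between(volumes$scan_date[i1], volumes$scan_date[i2])
    if (t < min_interval_months) {
      excl_id <- c(excl_id, pid)
      excl_reason <- c(excl_reason,
                       sprintf("interval %.2f months below minimum %.2f",
                               t, min_interval_months))
      next
    }
    first_i <- c(first_i, i1)
    last_i <- c(last_i, i2)
  }

  if (length(first_i)) {
    t <- months_between(volumes$scan_date[first_i],
                        volumes$scan_date[last_i])
    v1 <- volumes$volume_mm3[first_i]
    v2 <- volumes$volume_mm3[last_i]
    g <- growth_constant(v1, v2, t)
    res <- data.frame(patient_id = as.character(volumes$patient_id[first_i]),
                      v1_mm3 = v1, v2_mm3 = v2, interval_months = t,
                      delta_v_mm3 = v2 - v1, g_per_month = g,
                      tgr_pct_per_month = tumor_growth_rate(g),
                      stringsAsFactors = FALSE)
    res$progressed <- classify_progression(res)
  } else {
    res <- data.frame(patient_id = character(0), v1_mm3 = numeric(0),
                      v2_mm3 = numeric(0), interval_months = numeric(0),
                      delta_v_mm3 = numeric(0), g_per_month = numeric(0),
                      tgr_pct_per_month = numeric(0), progressed = logical(0),
                      stringsAsFactors = FALSE)
  }
  attr(res, "exclusions") <- data.frame(patient_id = excl_id,
                                        reason = excl_reason,
                                        stringsAsFactors = FALSE)
  res
}

#' Volumetric progression flag
#'
#' A patient has progressed if and only if the tumor volume increased between
#' baseline and the most recent scan, i.e. `delta_v > 0`, equivalently
#' `g > 0` or `TGR > 0`. An exactly unchanged volume is not progression
#' ("an increase" is read strictly).
#'
#' @param estimate data.frame with a `delta_v_mm3` column (a row or rows from
#'   [estimate_growth()]).
#' @return Logical vector.
#' @export
classify_progression <- function(estimate) {
  stopifnot(is.data.frame(estimate), "delta_v_mm3" %in% names(estimate))
  estimate$delta_v_mm3 > 0
}
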