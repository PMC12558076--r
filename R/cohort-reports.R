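# Cohort-level report builders: baseline-characteristics comparison,
# treatment-group kinetics comparison, lesion-location distribution and the
# symptom-onset rate.

#' Deguelte levels describing mesenteric-metastasis location
#'
#' Categorical levels describing the location of the mesenteric lymph node
#' metastasis relative to the superior mesenteric artery and its branches.
#' @export
MLNM_LEVELS <- c("I", "II", "III_down", "III_up", "IV")

#' Join patient records to growth estimates
#'
#' Inner join on `patient_id`; patients without a growth estimate (too few
#' scans or a sub-minimum interval) drop out.
#'
#' @param patients Patient table (see [read_patient_csv()]).
#' @param growth Output of [estimate_growth()].
#' @return Joined data.frame.
#' @export
join_growth <- function(patients, growth) {
  stopifnot(is.data.frame(patients), is.data.frame(growth))
  merge(patients, growth, by = "patient_id", sort = TRUE)
}

#' Location distribution of mesenteric metastases by symptom group
#'
#' Tabulates the Deguelte level within each symptom-at-diagnosis group.
#' Percentages are count / group size, rounded to the nearest integer for
#' reporting; an empty group reports zero counts and `NA` percentages.
#'
#' @param records Patient table with `mlnm_level` and `symptomatic_at_dx`.
#' @return data.frame with columns `mlnm_level`, `group`, `count`, `n_group`,
#'   `percent`.
#' @export
location_distribution <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("mlnm_level", "symptomatic_at_dx") %in% names(records)))
  lev <- as.character(records$mlnm_level)
  bad <- setdiff(unique(lev[!is.na(lev)]), MLNM_LEVELS)
  if (length(bad)) {
    stop("unknown mesenteric-location level(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(c(FALSE, TRUE), function(sym) {
    grp <- records[records$symptomatic_at_dx == sym, , drop = FALSE]
    n <- nrow(grp)
    counts <- vapply(MLNM_LEVELS,
                     function(l) sum(grp$mlnm_level == l, na.rm = TRUE),
                     integer(1))
    data.frame(mlnm_level = MLNM_LEVELS,
               group = if (sym) "symptomatic" else "asymptomatic",
               count = unname(counts), n_group = n,
               percent = if (n > 0) round(100 * unname(counts) / n) else
                 rep(NA_real_, length(MLNM_LEVELS)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Rate of symptom onset requiring surgery among initially asymptomatic patients
#'
#' @param records Patient table; only rows with `symptomatic_at_dx == FALSE`
#'   are counted.
#' @return List with `events`, `n`, `percent` (integer-rounded).
#' @export
symptom_onset_rate <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("symptomatic_at_dx", "symptom_surgery_event") %in%
                  names(records)))
  asym <- records[!records$symptomatic_at_dx, , drop = FALSE]
  if (nrow(asym) == 0L) {
    stop("no asymptomatic patients in cohort", call. = FALSE)
  }
  ev <- sum(asym$symptom_surgery_event, na.rm = TRUE)
  list(events = ev, n = nrow(asym), percent = round(100 * ev / nrow(asym)))
}

#' Kinetics comparison between treatment groups
#'
#' Median (Q1; Q3) of volume change and TGR in PRRT-treated versus untreated
#' patients, compared with the two-sided Mann-Whitney U test. By convention
#' the comparison is restricted to initially asymptomatic patients (the
#' treated subgroup of interest); pass `asymptomatic_only = FALSE` to use all.
#'
#' @param joined Output of [join_growth()] including `prrt_treated`.
#' @param asymptomatic_only Restrict to `symptomatic_at_dx == FALSE`
#'   (default TRUE).
#' @return data.frame with one row per quantity (`delta_v_mm3`,
#'   `tgr_pct_per_month`): group medians/quartiles, group sizes, p-value.
#' @export
prrt_comparison <- function(joined, asymptomatic_only = TRUE) {
  stopifnot(is.data.frame(joined),
            all(c("prrt_treated", "delta_v_mm3", "tgr_pct_per_month") %in%
                  names(joined)))
  d <- joined
  if (asymptomatic_only && "symptomatic_at_dx" %in% names(d)) {
    d <- d[!d$symptomatic_at_dx, , drop = FALSE]
  }
  trt <- d[d$prrt_treated == TRUE, , drop = FALSE]
  ctl <- d[d$prrt_treated == FALSE, , drop = FALSE]
  one <- function(col) {
    na3 <- c(median = NA_real_, q1 = NA_real_, q3 = NA_real_)
    mt <- if (nrow(trt)) median_iqr(trt[[col]]) else na3
    mc <- if (nrow(ctl)) median_iqr(ctl[[col]]) else na3
    p <- if (nrow(trt) && nrow(ctl))
      mann_whitney(trt[[col]], ctl[[col]])$p_value else NA_real_
    data.frame(quantity = col,
               treated_median = mt["median"], treated_q1 = mt["q1"],
               treated_q3 = mt["q3"], n_treated = nrow(trt),
               untreated_median = mc["median"], untreated_q1 = mc["q1"],
               untreated_q3 = mc["q3"], n_untreated = nrow(ctl),
               p_value = p, stringsAsFactors = FALSE)
  }
  out <- rbind(one("delta_v_mm3"), one("tgr_pct_per_month"))
  rownames(out) <- NULL
  out
}

#' Baseline-characteristics comparison by symptom group
#'
#' Builds a baseline table comparing asymptomatic and symptomatic patients:
#' continuous variables as median (Q1; Q3) with Mann-Whitney p-values,
#' binary variables as count (percent) with two-sided Fisher exact p-values,
#' and grade (three levels) with an r x c Fisher exact test.
#'
#' @param records Patient table.
#' @return data.frame with columns `variable`, `asymptomatic`, `symptomatic`,
#'   `p_value` (formatted strings for the group columns).
#' @export
summarize_baseline <- function(records) {
  stopifnot(is.data.frame(records), "symptomatic_at_dx" %in% names(records))
  a <- records[!records$symptomatic_at_dx, , drop = FALSE]
  s <- records[records$symptomatic_at_dx, , drop = FALSE]

  fmt_med <- function(x) {
    m <- median_iqr(x)
    sprintf("%.1f (%.1f-%.1f)", m["median"], m["q1"], m["q3"])
  }
  fmt_cnt <- function(k, n) sprintf("%d (%d)", k, round(100 * k / max(n, 1)))

  cont_row <- function(label, col) {
    ha <- any(is.finite(a[[col]])); hs <- any(is.finite(s[[col]]))
    data.frame(variable = label,
               asymptomatic = if (ha) fmt_med(a[[col]]) else "",
               symptomatic = if (hs) fmt_med(s[[col]]) else "",
               p_value = if (ha && hs)
                 mann_whitney(a[[col]], s[[col]])$p_value else NA_real_,
               stringsAsFactors = FALSE)
  }
  bin_row <- function(label, col, level = TRUE) {
    ka <- sum(a[[col]] == level, na.rm = TRUE)
    ks <- sum(s[[col]] == level, na.rm = TRUE)
    na <- sum(!is.na(a[[col]])); ns <- sum(!is.na(s[[col]]))
    p <- if (na > 0 && ns > 0)
      fisher_exact_2x2(matrix(c(ka, na - ka, ks, ns - ks), nrow = 2,
                              byrow = TRUE)) else NA_real_
    data.frame(variable = label,
               asymptomatic = if (na > 0) fmt_cnt(ka, na) else "",
               symptomatic = if (ns > 0) fmt_cnt(ks, ns) else "",
               p_value = p, stringsAsFactors = FALSE)
  }

  rows <- list(
    cont_row("age_years", "age"),
    bin_row("sex_female", "sex", "female"),
    bin_row("deceased", "death_event"),
    bin_row("liver_mets", "liver_mets"),
    bin_row("peritoneal_mets", "peritoneal_mets"),
    bin_row("extraabdominal_mets", "extraabdominal_mets"),
    cont_row("u5hiaa_umol_dl", "u5hiaa"),
    cont_row("ki67_pct", "ki67"),
    bin_row("carcinoid_heart", "carcinoid_heart"))

  # grade is 3-level; r x c Fisher exact (in-package routine is 2x2 by contract)
  ga <- table(factor(a$grade, levels = c(1, 2, 3)))
  gs <- table(factor(s$grade, levels = c(1, 2, 3)))
  tab <- cbind(as.integer(ga), as.integer(gs))
  keep <- rowSums(tab) > 0
  p_grade <- if (sum(keep) >= 2 && all(colSums(tab) > 0)) {
    stats::fisher.test(tab[keep, , drop = FALSE])$p.value
  } else NA_real_
  rows <- c(rows, list(data.frame(
    variable = "grade_1_2_3",
    asymptomatic = paste(as.integer(ga), collapse = "/"),
    symptomatic = paste(as.integer(gs), collapse = "/"),
    p_value = p_grade, stringsAsFactors = FALSE)))

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
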