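# Independent oracles and small fixture builders used across the suite.

# brute-force product-limit oracle: for a query time t, walk the distinct
# event times from scratch and multiply the factors directly
km_oracle_at <- function(times, events, t) {
  ev_times <- sort(unique(times[as.logical(events)]))
  s <- 1
  for (ti in ev_times) {
    if (ti > t) break
    d <- sum(times == ti & as.logical(events))
    n <- sum(times >= ti)
    s <- s * (1 - d / n)
  }
  s
}

# exact Mann-Whitney oracle: enumerate every assignment of pooled values to
# group A and recompute U from scratch per assignment
mw_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  mu <- n * length(b) / 2
  combos <- utils::combn(length(pooled), n)
  u_all <- apply(combos, 2, u_of)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-8)
}

# minimal patient table with every schema column, all defaults overridable
make_patients <- function(n, symptomatic = FALSE, ...) {
  out <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = rep(70, n), sex = rep("male", n),
    symptomatic_at_dx = rep(symptomatic, length.out = n),
    grade = rep(1L, n), ki67 = rep(4, n), u5hiaa = rep(300, n),
    carcinoid_heart = FALSE, liver_mets = TRUE, peritoneal_mets = FALSE,
    extraabdominal_mets = FALSE, prrt_treated = FALSE,
    mlnm_level = rep("I", n),
    t_symptom_surgery_months = rep(60, n), symptom_surgery_event = FALSE,
    t_death_months = rep(60, n), death_event = FALSE,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

# two-scan lesion table realising given volumes as spheres
make_lesions <- function(patient_id, dates, volumes) {
  d <- (6 * volumes / pi)^(1 / 3)
  data.frame(patient_id = patient_id, scan_date = as.Date(dates),
             d_transverse_mm = d, d_coronal_mm = d, d_sagittal_mm = d,
             is_conglomerate = rep(0L, length(volumes)),
             stringsAsFactors = FALSE)
}
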