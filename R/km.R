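# Kaplan-Meier product-limit estimation with Greenwood variance and
# log-log 95% confidence intervals.

#' Kaplan-Meier product-limit fit
#'
#' Estimates the survival function under right censoring:
#' \deqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}
#' over the distinct event times `t_i` with `d_i` events among `n_i` at risk.
#' The variance is Greenwood's formula and the 95% confidence interval is
#' computed on the complementary log-log scale
#' (`log(-log S)` +/- 1.96 standard errors, back-transformed), the transform
#' that keeps the bounds inside \[0, 1\].
#'
#' @param times Non-negative follow-up times (months).
#' @param events Logical (or 0/1) event indicators; `FALSE` = censored.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `km_curve`: a list with `time` (distinct event
#'   times, increasing), `n_risk`, `n_event`, `survival`, `greenwood_var`,
#'   `ci_low`, `ci_high`, plus `n` and `n_events` totals.
#' @export
km_fit <- function(times, events, conf_level = 0.95) {
  if (length(times) != length(events)) {
    stop("'times' and 'events' must have equal length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be non-negative and finite", call. = FALSE)
  }
  ev <- as.logical(events)
  if (any(is.na(ev))) stop("events must be logical or 0/1", call. = FALSE)

  tu <- sort(unique(times[ev]))
  n_risk <- n_event <- integer(length(tu))
  surv <- gw <- numeric(length(tu))
  s <- 1
  gw_sum <- 0
  for (i in seq_along(tu)) {
    n_risk[i] <- sum(times >= tu[i])
    n_event[i] <- sum(times == tu[i] & ev)
    s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
    if (n_risk[i] > n_event[i]) {
      gw_sum <- gw_sum + n_event[i] / (n_risk[i] * (n_risk[i] - n_event[i]))
    } else {
      gw_sum <- Inf
    }
    gw[i] <- s^2 * gw_sum
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci_low <- ci_high <- rep(NA_real_, length(tu))
  pos <- which(surv > 0 & surv < 1 & is.finite(gw))
  if (length(pos)) {
    se_cll <- sqrt(gw[pos]) / (surv[pos] * abs(log(surv[pos])))
    ci_low[pos] <- surv[pos]^exp(z * se_cll)
    ci_high[pos] <- surv[pos]^exp(-z * se_cll)
  }
  ci_low[surv == 0] <- 0
  ci_high[surv == 0] <- 0
  structure(list(time = tu, n_risk = n_risk, n_event = n_event,
                 survival = surv, greenwood_var = gw,
                 ci_low = ci_low, ci_high = ci_high,
                 n = length(times), n_events = sum(ev),
                 conf_level = conf_level),
            class = "km_curve")
}

#' Survival probability at given times
#'
#' Evaluates the right-continuous Kaplan-Meier step function.
#'
#' @param fit A `km_curve` from [km_fit()].
#' @param t Times (months) at which to evaluate.
#' @return Survival probabilities.
#' @export
km_survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "km_curve"))
  vapply(t, function(ti) {
    i <- sum(fit$time <= ti)
    if (i == 0L) 1 else fit$survival[i]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d\n", x$n, x$n_events))
  print(as.data.frame.km_curve(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time_months = x$time, n_at_risk = x$n_risk,
             n_event = x$n_event, survival = x$survival,
             ci_low = x$ci_low, ci_high = x$ci_high)
}
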