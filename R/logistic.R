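# Logistic model for volumetric progression with listwise deletion and
# per-term separation reporting.

#' Logistic regression for volumetric progression
#'
#' Fits, by maximum likelihood, the model used to screen clinical covariates
#' for association with volumetric progression:
#' `progressed ~ age + sex + u5hiaa + ki67 + grade`, with male the reference
#' sex and grade 1 the reference grade. Records with any missing covariate
#' are removed first (listwise deletion) and the removal count is reported.
#' Odds ratios are exponentiated coefficients with Wald 95% confidence
#' intervals.
#'
#' Complete or quasi-complete separation (e.g. a grade level with no
#' progressors) makes the affected coefficient non-identifiable; such terms
#' are reported with an odds ratio driven to 0 or infinity, a (0, Inf)
#' confidence interval and `identifiable = FALSE`, rather than failing.
#'
#' @param data data.frame with columns `progressed` (logical/0-1), `age`,
#'   `sex` ("female"/"male"), `u5hiaa`, `ki67`, `grade` (1, 2, 3 or NA).
#' @param covariates Character vector of covariate columns to include
#'   (default the five above).
#' @return Object of class `logistic_fit`: list with `terms` (data.frame:
#'   `term`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `identifiable`),
#'   `n_used`, `n_excluded`, `exclusions` (per-record missing fields), and
#'   `outcome_varies`.
#' @export
logistic_progression <- function(data,
                                 covariates = c("age", "sex", "u5hiaa",
                                                "ki67", "grade")) {
  stopifnot(is.data.frame(data), "progressed" %in% names(data),
            all(covariates %in% names(data)))
  n_total <- nrow(data)

  d <- data
  d$progressed <- as.logical(d$progressed)
  if ("sex" %in% covariates) {
    d$sex <- factor(as.character(d$sex), levels = c("male", "female"))
  }
  if ("grade" %in% covariates) {
    d$grade <- factor(as.character(d$grade), levels = c("1", "2", "3"))
  }

  miss <- lapply(seq_len(n_total), function(i) {
    fields <- covariates[vapply(covariates,
                                function(cv) is.na(d[[cv]][i]), logical(1))]
    if (is.na(d$progressed[i])) fields <- c(fields, "progressed")
    fields
  })
  drop <- vapply(miss, function(f) length(f) > 0L, logical(1))
  exclusions <- data.frame(
    row = which(drop),
    missing = vapply(miss[drop], paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  if ("patient_id" %in% names(d) && nrow(exclusions)) {
    exclusions$patient_id <- as.character(d$patient_id[drop])
  }
  d <- d[!drop, , drop = FALSE]
  n_used <- nrow(d)

  outcome_varies <- length(unique(d$progressed)) == 2L

  # a covariate with a single observed value carries no information and
  # breaks the model matrix; fit without it and report it non-identifiable
  constant <- covariates[vapply(covariates, function(cv) {
    length(unique(d[[cv]][!is.na(d[[cv]])])) < 2L
  }, logical(1))]
  used <- setdiff(covariates, constant)
  rhs <- if (length(used)) paste(used, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("progressed ~", rhs))
  fit <- suppressWarnings(stats::glm(fml, data = d,
                                     family = stats::binomial()))
  cf <- summary(fit)$coefficients
  # aliased coefficients (unused factor level, collinearity) are dropped from
  # the summary; reinstate them as non-identifiable terms in model order
  term <- names(stats::coef(fit))
  beta <- se <- p <- rep(NA_real_, length(term))
  names(beta) <- names(se) <- names(p) <- term
  beta[rownames(cf)] <- cf[, "Estimate"]
  se[rownames(cf)] <- cf[, "Std. Error"]
  p[rownames(cf)] <- cf[, "Pr(>|z|)"]
  aliased <- is.na(beta)
  z <- stats::qnorm(0.975)

  # separation heuristic: an absurd Wald SE on the log-odds scale means the
  # likelihood is flat in that direction (coefficient escaping to +/- Inf)
  sep <- aliased | se > 50 | abs(beta) > 15
  if (!outcome_varies) sep[] <- TRUE
  sep[is.na(sep)] <- TRUE
  or <- exp(beta)
  lo <- exp(beta - z * se)
  hi <- exp(beta + z * se)
  or[sep] <- ifelse(!is.na(beta[sep]) & beta[sep] < 0, 0, Inf)
  or[aliased] <- NA_real_
  lo[sep] <- 0
  hi[sep] <- Inf

  terms <- data.frame(term = unname(term), odds_ratio = unname(or),
                      ci_low = unname(lo), ci_high = unname(hi),
                      p_value = unname(p), identifiable = unname(!sep),
                      stringsAsFactors = FALSE)
  if (length(constant)) {
    dropped <- lapply(constant, function(cv) {
      nm <- if (is.factor(d[[cv]])) {
        paste0(cv, setdiff(levels(d[[cv]]), levels(d[[cv]])[1]))
      } else cv
      data.frame(term = nm, odds_ratio = NA_real_, ci_low = 0,
                 ci_high = Inf, p_value = NA_real_, identifiable = FALSE,
                 stringsAsFactors = FALSE)
    })
    terms <- rbind(terms, do.call(rbind, dropped))
  }
  structure(list(terms = terms, n_used = n_used,
                 n_excluded = n_total - n_used, exclusions = exclusions,
                 outcome_varies = outcome_varies,
                 converged = fit$converged && outcome_varies && !any(sep)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic progression model (n = %d; %d excluded for missing data)\n",
              x$n_used, x$n_excluded))
  if (!x$outcome_varies) {
    cat("Outcome shows no variation: fit is non-identifiable.\n")
  }
  t <- x$terms
  t$odds_ratio <- signif(t$odds_ratio, 4)
  t$ci_low <- signif(t$ci_low, 4)
  t$ci_high <- signif(t$ci_high, 4)
  t$p_value <- round(t$p_value, 3)
  print(t, row.names = FALSE)
  invisible(x)
}
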