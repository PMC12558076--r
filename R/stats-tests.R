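# Descriptive summaries and the two group-comparison tests used in the
# cohort reports: Mann-Whitney U (continuous rows) and Fisher's exact
# (2x2 categorical rows).

#' Median and interquartile range
#'
#' Missing values are dropped first; quantiles use linear interpolation
#' between order statistics (type 7, the common default).
#'
#' @param values Numeric vector with at least one finite value.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0L) {
    stop("no finite values left after dropping missing", call. = FALSE)
  }
  q <- stats::quantile(v, probs = c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Mann-Whitney U test (two-sided)
#'
#' U is the rank-sum statistic for `group_a` (midranks under ties). For group
#' sizes of at most 8 each, the two-sided p-value is exact: all
#' `choose(n+m, n)` assignments of the pooled values to group A are
#' enumerated and the p-value is the proportion whose U is at least as far
#' from the null mean `n*m/2` as the observed U. For larger groups the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List with `U`, `p_value`, and `method` ("exact" or "normal").
#' @export
mann_whitney <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) {
    stop("both groups must contain at least one finite value", call. = FALSE)
  }
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  if (n <= 8L && m <= 8L) {
    # exact enumeration over subsets of pooled positions assigned to group A
    idx <- utils::combn(n + m, n)
    u_all <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    eps <- 1e-8
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - eps)
    method <- "exact"
  } else {
    nm <- n + m
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nm * (nm - 1))
    sigma <- sqrt(n * m / 12 * (nm + 1 - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sigma
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal"
  }
  list(U = u_obs, p_value = p, method = method)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' The two-sided p-value sums, over the hypergeometric support with the
#' observed margins, every table probability not exceeding the observed
#' table's probability (the standard "probability" method).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.matrix(table)
  if (!all(dim(x) == c(2L, 2L))) {
    stop("expected a 2x2 table", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0) || any(abs(x - round(x)) > 1e-8)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  x <- round(x)
  m <- sum(x[1, ])            # row-1 margin
  n <- sum(x[2, ])            # row-2 margin
  k <- sum(x[, 1])            # column-1 margin
  if (m + n == 0L || k == 0L || k == m + n) return(1)
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
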