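# Scalar test-retest agreement: two-way ANOVA mean squares, the
# single-measure absolute-agreement intraclass correlation ICC(A,1)
# with its F-based confidence interval (McGraw & Wong 1996, the
# construction SPSS uses), a significance test against ICC = 0, the
# Cicchetti reliability categories, and Bland-Altman limits of
# agreement.
#
# ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))
#
# where MSR, MSC, MSE are the row (subject), column (session) and error
# mean squares of the two-way crossed decomposition on the n complete
# subjects and k sessions.

#' Two-way crossed ANOVA mean squares of a metric table
#'
#' Decomposes the complete-case n x k table into subject (row), session
#' (column) and error mean squares:
#' `SSR = k * sum_i (rowmean_i - grand)^2`,
#' `SSC = n * sum_j (colmean_j - grand)^2`, `SSE = SST - SSR - SSC`;
#' `MSR = SSR/(n-1)`, `MSC = SSC/(k-1)`, `MSE = SSE/((n-1)(k-1))`.
#' A tiny negative SSE from floating-point cancellation is clamped to 0.
#'
#' @param t A `metric_table` with at least 3 complete subjects.
#' @return Named list with `msr`, `msc`, `mse`, `n`, `k`.
#' @export
#' @examples
#' t <- metric_table(rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8)))
#' anova_mean_squares(t)  # msr = 40/3, msc = 2, mse = 0
anova_mean_squares <- function(t) {
  v <- complete_values(t)
  n <- nrow(v)
  k <- ncol(v)
  grand <- mean(v)
  rm <- rowMeans(v)
  cm <- colMeans(v)
  ssr <- k * sum((rm - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((v - grand)^2)
  sse <- sst - ssr - ssc
  if (sse < -1e-9) stop("negative error sum of squares: ", sse)
  sse <- max(sse, 0)
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' ICC(A,1): single-measure absolute-agreement intraclass correlation
#'
#' Point estimate of the two-way-model absolute-agreement ICC for a
#' single measurement, computed from the complete rows of the table.
#' May be negative; 1 exactly when there is no session or error
#' variance.
#'
#' @param t A `metric_table`.
#' @return Estimate (numeric scalar), with the mean squares attached as
#'   attribute `ms`.
#' @export
#' @examples
#' t <- metric_table(rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8)))
#' icc_a1(t)  # 40/43
icc_a1 <- function(t) {
  ms <- anova_mean_squares(t)
  denom <- ms$msr + (ms$k - 1) * ms$mse + (ms$k / ms$n) * (ms$msc - ms$mse)
  if (denom == 0) {
    stop("ICC undefined: all cells identical (zero total variance)")
  }
  est <- (ms$msr - ms$mse) / denom
  attr(est, "ms") <- ms
  est
}

#' F-based confidence interval for ICC(A,1)
#'
#' Two-sided `(1 - alpha)` interval using the F-distribution
#' construction with Satterthwaite-approximated denominator degrees of
#' freedom (McGraw & Wong 1996), as reported by SPSS.
#'
#' @param t A `metric_table`.
#' @param alpha Significance level (default 0.05 for a 95% interval).
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
icc_confidence_interval <- function(t, alpha = 0.05) {
  est <- icc_a1(t)
  ms <- attr(est, "ms")
  est <- as.numeric(est)
  n <- ms$n; k <- ms$k
  if (ms$mse == 0 && ms$msc == 0) {
    warning("no session or error variance: degenerate interval [1, 1]")
    return(c(1, 1))
  }
  a <- (k * est) / (n * (1 - est))
  b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (ms$msr - f_l * ms$mse) /
    (f_l * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  upper <- n * (f_u * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * f_u * ms$msr)
  c(lower, upper)
}

#' Significance of ICC(A,1) against zero
#'
#' One-sided p-value from `F = MSR / MSE` on `(n - 1, (n - 1)(k - 1))`
#' degrees of freedom, the test SPSS reports alongside the ICC.
#'
#' @param t A `metric_table`.
#' @return p-value in `[0, 1]`.
#' @export
icc_significance <- function(t) {
  ms <- anova_mean_squares(t)
  if (ms$mse == 0) {
    warning("zero error mean square: p-value degenerate at 0")
    return(0)
  }
  f <- ms$msr / ms$mse
  pf(f, ms$n - 1, (ms$n - 1) * (ms$k - 1), lower.tail = FALSE)
}

#' Cicchetti reliability category of an ICC estimate
#'
#' Excellent for ICC >= 0.75, good for `[0.60, 0.75)`, fair for
#' `[0.40, 0.60)`, poor below 0.40 (negative estimates are poor). The
#' published bins leave `[0.74, 0.75]` ambiguous; half-open bins with
#' excellent at >= 0.75 close the gap.
#'
#' @param icc ICC estimate, at most 1.
#' @return One of `"excellent"`, `"good"`, `"fair"`, `"poor"`.
#' @export
classify_icc <- function(icc) {
  if (!is.numeric(icc) || length(icc) != 1L || is.na(icc)) {
    stop("icc must be a single number")
  }
  if (icc > 1 + 1e-12) stop("icc cannot exceed 1, got ", icc)
  if (icc >= 0.75) "excellent"
  else if (icc >= 0.60) "good"
  else if (icc >= 0.40) "fair"
  else "poor"
}

#' Full ICC(A,1) analysis of one metric table
#'
#' Convenience wrapper returning the estimate, confidence interval,
#' significance, mean squares and reliability category in one object.
#'
#' @param t A `metric_table`.
#' @param alpha Level for the confidence interval.
#' @return Object of class `icc_result`.
#' @export
icc_report <- function(t, alpha = 0.05) {
  est <- icc_a1(t)
  ms <- attr(est, "ms")
  est <- as.numeric(est)
  ci <- suppressWarnings(icc_confidence_interval(t, alpha))
  p <- suppressWarnings(icc_significance(t))
  structure(
    list(icc = est, ci_low = ci[1], ci_high = ci[2], p_value = p,
         msr = ms$msr, msc = ms$msc, mse = ms$mse,
         n = ms$n, k = ms$k, category = classify_icc(est),
         bundle = t$bundle, metric = t$metric),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result %s/%s> ICC(A,1) = %.3f [%.3f, %.3f], p = %.3g, %s (n = %d)\n",
              x$bundle, x$metric, x$icc, x$ci_low, x$ci_high, x$p_value,
              x$category, x$n))
  invisible(x)
}

#' Bland-Altman agreement analysis of a paired-session table
#'
#' Differences are session 1 minus session 2. Limits of agreement are
#' the mean difference plus/minus `m` sample standard deviations of the
#' differences (`m = 2` by default, as conventionally drawn on the
#' plots). `fraction_within` is the proportion of pairs inside the
#' limits; agreement is called good when it is at least 0.95. Because
#' that rule is coarse at small n (with n = 18 the strictest attainable
#' non-unity fraction is 17/18), the integer count outside the limits
#' is reported as well.
#'
#' @param t A `metric_table` with exactly 2 sessions and at least 3
#'   complete subjects.
#' @param m Limits-of-agreement SD multiplier.
#' @return Object of class `bland_altman_result` with fields
#'   `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `fraction_within`,
#'   `n_outside`, `good_agreement`, `pair_means`, `pair_diffs`, `n`.
#' @export
#' @examples
#' t <- metric_table(rbind(c(1, 2), c(2, 2), c(3, 5)))
#' bland_altman(t)  # mean -1, sd 1, limits (-3, 1)
bland_altman <- function(t, m = 2.0) {
  stopifnot(inherits(t, "metric_table"))
  if (t$k != 2L) stop("Bland-Altman analysis needs exactly 2 sessions")
  v <- complete_values(t)
  d <- v[, 1L] - v[, 2L]
  mu <- mean(d)
  s <- sd(d)
  loa <- c(mu - m * s, mu + m * s)
  inside <- d >= loa[1] & d <= loa[2]
  frac <- mean(inside)
  structure(
    list(mean_diff = mu, sd_diff = s, loa_low = loa[1], loa_high = loa[2],
         fraction_within = frac, n_outside = sum(!inside),
         good_agreement = frac >= 0.95,
         pair_means = rowMeans(v), pair_diffs = d, n = nrow(v),
         bundle = t$bundle, metric = t$metric),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman_result %s/%s> mean diff %.4g, LoA [%.4g, %.4g], %d/%d within (%s)\n",
              x$bundle, x$metric, x$mean_diff, x$loa_low, x$loa_high,
              round(x$fraction_within * x$n), x$n,
              if (x$good_agreement) "good agreement" else "outliers beyond limits"))
  invisible(x)
}
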