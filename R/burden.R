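# Weighted carrier-frequency point estimates and exact-style confidence
# intervals on fractional (weighted) carrier counts.

#' Weighted carrier frequency as a percentage
#'
#' @param weighted_x weighted carrier count (sum of per-individual combined
#'   weights), 0 <= weighted_x <= n.
#' @param n cohort sample size (> 0).
#' @return carrier frequency in percent.
#' @export
weighted_frequency <- function(weighted_x, n) {
  if (length(n) != 1L || is.na(n) || n <= 0) stop("n must be a positive count")
  stopifnot(weighted_x >= 0, weighted_x <= n)
  100 * weighted_x / n
}

#' Generalized Clopper-Pearson interval for a weighted carrier count
#'
#' Exact-style binomial interval extended to fractional effective counts via
#' beta quantiles: the lower limit is the `alpha/2` quantile of
#' Beta(x, n - x + 1) and the upper limit the `1 - alpha/2` quantile of
#' Beta(x + 1, n - x). At integer `x` this is the classic Clopper-Pearson
#' interval; the endpoints are exactly 0 at `x = 0` and 1 (i.e. 100 percent)
#' at `x = n`.
#'
#' @param weighted_x weighted carrier count, 0 <= weighted_x <= n.
#' @param n sample size (> 0).
#' @param level confidence level in (0, 1).
#' @return named numeric vector `c(low, high)` in percent.
#' @export
frequency_ci <- function(weighted_x, n, level = 0.95) {
  if (length(n) != 1L || is.na(n) || n <= 0) stop("n must be a positive count")
  stopifnot(weighted_x >= 0, weighted_x <= n)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)")
  alpha <- 1 - level
  low <- if (weighted_x <= 0) 0 else {
    stats::qbeta(alpha / 2, weighted_x, n - weighted_x + 1)
  }
  high <- if (weighted_x >= n) 1 else {
    stats::qbeta(1 - alpha / 2, weighted_x + 1, n - weighted_x)
  }
  c(low = 100 * low, high = 100 * high)
}

#' Cohort burden summary for one count
#'
#' Convenience wrapper assembling the point estimate and interval into the
#' cohort-summary row format.
#'
#' @inheritParams frequency_ci
#' @param cohort_id,group_name labels for the row.
#' @return one-row data.frame (`cohort_id`, `group_name`, `weighted_x`, `n`,
#'   `percent`, `ci_low`, `ci_high`).
#' @export
burden_summary <- function(weighted_x, n, cohort_id = "cohort",
                           group_name = "ALL", level = 0.95) {
  ci <- frequency_ci(weighted_x, n, level)
  data.frame(cohort_id = cohort_id, group_name = group_name,
             weighted_x = weighted_x, n = n,
             percent = weighted_frequency(weighted_x, n),
             ci_low = ci[["low"]], ci_high = ci[["high"]],
             stringsAsFactors = FALSE)
}
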