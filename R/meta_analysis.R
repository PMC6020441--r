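# Random-effects meta-analysis of (possibly weighted) carrier proportions:
# Freeman-Tukey double-arcsine transform, DerSimonian-Laird pooling, and
# Miller's harmonic-mean back-transform. Weighted carrier counts need not be
# integers; all formulas accept fractional x.

#' Freeman-Tukey double-arcsine transform
#'
#' Variance-stabilizing transform for a binomial-type proportion:
#' \eqn{y = \arcsin\sqrt{x/(n+1)} + \arcsin\sqrt{(x+1)/(n+1)}} with sampling
#' variance \eqn{v = 1/(n + 1/2)}. Defined at x = 0 and x = n without
#' continuity corrections, which is the point of using it with zero-carrier
#' studies.
#'
#' @param x carrier count (weighted counts allowed), 0 <= x <= n.
#' @param n sample size (> 0).
#' @return named list `y` (transformed value, radians) and `v` (variance).
#' @export
ft_transform <- function(x, n) {
  if (any(x < 0) || any(x > n)) stop("x must satisfy 0 <= x <= n")
  stopifnot(all(n > 0))
  y <- asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1)))
  list(y = y, v = 1 / (n + 0.5))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance: with fixed-effect weights
#' \eqn{w_i = 1/v_i} and \eqn{Q = \sum w_i (y_i - \bar y_{FE})^2},
#' \eqn{\tau^2 = \max(0, (Q - df) / (\sum w_i - \sum w_i^2 / \sum w_i))};
#' random-effects weights are \eqn{w_i^* = 1/(v_i + \tau^2)}. A single study
#' is returned as-is with \eqn{\tau^2 = 0}.
#'
#' @param y numeric vector of transformed study estimates.
#' @param v numeric vector of their sampling variances (> 0).
#' @return list `pooled_y`, `se`, `tau2`, `Q`.
#' @export
pool_random_effects <- function(y, v) {
  k <- length(y)
  if (k == 0L) stop("at least one study required")
  stopifnot(length(v) == k, all(v > 0))
  if (k == 1L) return(list(pooled_y = y, se = sqrt(v), tau2 = 0, Q = 0))
  w <- 1 / v
  y_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - y_fe)^2)
  df <- k - 1
  c_denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - df) / c_denom)
  w_star <- 1 / (v + tau2)
  pooled_y <- sum(w_star * y) / sum(w_star)
  list(pooled_y = pooled_y, se = 1 / sqrt(sum(w_star)), tau2 = tau2, Q = Q)
}

# Miller's inverse of the double-arcsine transform at harmonic-mean n.
# t is on the scale of ft_transform (0..pi); values outside the achievable
# range for the given n map to the boundary proportions.
.ft_invert <- function(t, n_harm) {
  if (t <= 0) return(0)
  if (t >= pi) return(1)
  s <- sin(t)
  if (s == 0) return(if (t < pi / 2) 0 else 1)
  inner <- s + (s - 1 / s) / n_harm
  rad <- 1 - inner^2
  if (rad < 0) return(if (cos(t) > 0) 0 else 1)
  p <- 0.5 * (1 - sign(cos(t)) * sqrt(rad))
  min(1, max(0, p))
}

#' Back-transform a pooled double-arcsine value to a proportion
#'
#' Uses Miller's closed-form inversion evaluated at the harmonic mean of the
#' study sample sizes. Confidence limits are back-transformed from the
#' normal-theory limits on the transformed scale and clamped to [0, 1].
#'
#' @param pooled_y pooled transformed value.
#' @param se its standard error.
#' @param n_list vector of study sample sizes (harmonic mean taken).
#' @param level confidence level.
#' @return named list `percent`, `ci_low`, `ci_high` (percent scale).
#' @export
ft_back_transform <- function(pooled_y, se, n_list, level = 0.95) {
  if (!length(n_list)) stop("n_list must be non-empty")
  if (level <= 0 || level >= 1) stop("level must be in (0,1)")
  n_harm <- length(n_list) / sum(1 / n_list)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- .ft_invert(pooled_y, n_harm)
  lo <- .ft_invert(pooled_y - z * se, n_harm)
  hi <- .ft_invert(pooled_y + z * se, n_harm)
  list(percent = 100 * p, ci_low = 100 * lo, ci_high = 100 * hi)
}

#' Random-effects meta-analysis of carrier proportions
#'
#' Pools per-study (weighted) carrier counts via the Freeman-Tukey transform
#' under a DerSimonian-Laird random-effects model and back-transforms with
#' Miller's harmonic-mean inversion. The p-value is a two-sided normal test
#' of the pooled transformed value against the transform of a zero
#' proportion at the harmonic-mean sample size (test that the pooled carrier
#' proportion exceeds zero).
#'
#' @param studies data.frame with columns `study_id`, `x` (weighted carrier
#'   count) and `n` (sample size).
#' @param level confidence level.
#' @param group_name label carried into the result row.
#' @return one-row data.frame: `group_name`, `k`, `pooled_percent`, `ci_low`,
#'   `ci_high`, `tau2`, `Q`, `I2`, `p_value`.
#' @export
meta_proportion <- function(studies, level = 0.95, group_name = "ALL") {
  stopifnot(is.data.frame(studies), nrow(studies) >= 1,
            all(c("x", "n") %in% names(studies)))
  if (any(studies$x < 0) || any(studies$x > studies$n)) {
    stop("study counts must satisfy 0 <= x <= n")
  }
  ft <- ft_transform(studies$x, studies$n)
  pooled <- pool_random_effects(ft$y, ft$v)
  bt <- ft_back_transform(pooled$pooled_y, pooled$se, studies$n, level)
  k <- nrow(studies)
  df <- k - 1
  I2 <- if (k > 1 && pooled$Q > 0) max(0, 100 * (pooled$Q - df) / pooled$Q) else 0
  n_harm <- k / sum(1 / studies$n)
  y0 <- ft_transform(0, n_harm)$y
  zstat <- (pooled$pooled_y - y0) / pooled$se
  p_value <- min(1, 2 * stats::pnorm(-abs(zstat)))
  data.frame(group_name = group_name, k = k,
             pooled_percent = bt$percent, ci_low = bt$ci_low,
             ci_high = bt$ci_high, tau2 = pooled$tau2, Q = pooled$Q, I2 = I2,
             p_value = p_value, stringsAsFactors = FALSE)
}

#' Forest table: per-study rows plus the pooled row
#'
#' Tabular equivalent of a forest plot: each study's proportion with a
#' generalized Clopper-Pearson interval, then the pooled random-effects row
#' with heterogeneity statistics.
#'
#' @inheritParams meta_proportion
#' @return data.frame with one row per study and a final `POOLED` row.
#' @export
forest_table <- function(studies, level = 0.95, group_name = "ALL") {
  rows <- lapply(seq_len(nrow(studies)), function(i) {
    ci <- frequency_ci(studies$x[i], studies$n[i], level)
    data.frame(group_name = group_name, study_id = as.character(studies$study_id[i]),
               x = studies$x[i], n = studies$n[i],
               percent = weighted_frequency(studies$x[i], studies$n[i]),
               ci_low = ci[["low"]], ci_high = ci[["high"]],
               tau2 = NA_real_, I2 = NA_real_, p_value = NA_real_,
               stringsAsFactors = FALSE)
  })
  meta <- meta_proportion(studies, level, group_name)
  pooled_row <- data.frame(group_name = group_name, study_id = "POOLED",
                           x = sum(studies$x), n = sum(studies$n),
                           percent = meta$pooled_percent,
                           ci_low = meta$ci_low, ci_high = meta$ci_high,
                           tau2 = meta$tau2, I2 = meta$I2,
                           p_value = meta$p_value, stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), pooled_row)
  rownames(out) <- NULL
  out
}
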