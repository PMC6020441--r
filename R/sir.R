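# Standardized incidence ratios of weighted carrier burden in cases versus a
# reference population, with exact Poisson inference generalized to
# fractional observed counts through the gamma distribution.

#' Expected carrier count from a reference proportion
#'
#' @param p_ref reference-population carrier proportion in [0, 1].
#' @param n_cases number of cases (> 0).
#' @return expected (weighted) carrier count among the cases.
#' @export
expected_count <- function(p_ref, n_cases) {
  stopifnot(p_ref >= 0, p_ref <= 1, n_cases > 0)
  p_ref * n_cases
}

#' Exact (Garwood-type) Poisson confidence interval on a count
#'
#' Gamma-quantile form of the exact interval for a Poisson mean given an
#' observed count O: lower limit the `alpha/2` quantile of Gamma(O, 1),
#' upper limit the `1 - alpha/2` quantile of Gamma(O + 1, 1). The lower
#' limit is 0 when O = 0. Fractional (weighted) observed counts are handled
#' by the same gamma expressions.
#'
#' @param observed observed count (>= 0; fractional allowed).
#' @param level confidence level in (0, 1).
#' @return named numeric `c(low, high)` on the count scale.
#' @export
poisson_exact_interval <- function(observed, level = 0.95) {
  stopifnot(observed >= 0)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)")
  alpha <- 1 - level
  low <- if (observed <= 0) 0 else stats::qgamma(alpha / 2, shape = observed)
  high <- stats::qgamma(1 - alpha / 2, shape = observed + 1)
  c(low = low, high = high)
}

# Poisson tail probabilities with fractional counts via the gamma identity:
# P(X >= k) = pgamma(lambda, k)   and   P(X <= k) = 1 - pgamma(lambda, k + 1)
# (equalities exact at integer k; the gamma form interpolates between them).
.pois_upper_tail <- function(observed, lambda) {
  if (observed <= 0) return(1)
  stats::pgamma(lambda, shape = observed)
}
.pois_lower_tail <- function(observed, lambda) {
  stats::pgamma(lambda, shape = observed + 1, lower.tail = FALSE)
}

#' Standardized incidence ratio with exact Poisson inference
#'
#' SIR = observed / expected, with the confidence interval obtained by
#' dividing the exact Poisson interval on the observed count by the expected
#' count, and a two-sided exact p-value
#' \eqn{2 \min(P(X \le O), P(X \ge O))} (capped at 1) under
#' \eqn{X \sim Poisson(E)}. Weighted (fractional) observed counts use the
#' gamma-tail generalization of the Poisson tails.
#'
#' @param observed observed (weighted) carrier count among cases.
#' @param expected expected count from the reference proportion (> 0).
#' @param level confidence level.
#' @param group_name label carried into the result row.
#' @return one-row data.frame: `group_name`, `observed`, `expected`, `sir`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
sir_test <- function(observed, expected, level = 0.95, group_name = "ALL") {
  stopifnot(observed >= 0)
  if (expected <= 0) stop("expected count must be positive")
  ci <- poisson_exact_interval(observed, level)
  p <- min(1, 2 * min(.pois_lower_tail(observed, expected),
                      .pois_upper_tail(observed, expected)))
  data.frame(group_name = group_name, observed = observed,
             expected = expected, sir = observed / expected,
             ci_low = ci[["low"]] / expected, ci_high = ci[["high"]] / expected,
             p_value = p, stringsAsFactors = FALSE)
}

#' SIR table across gene groups
#'
#' For each gene group, compares the cases' pooled weighted carrier count
#' against the count expected under the reference population's proportion
#' (the reference burden must be graded with the same weighting scheme as
#' the cases).
#'
#' @param case_counts data.frame with columns `group_name` and `weighted_x`
#'   (summed over cohorts) for the cases.
#' @param n_cases total number of cases.
#' @param reference reference summary from [read_reference_summary()] (list
#'   with `n_ref` and `weighted_carriers_by_group`).
#' @param level confidence level.
#' @return data.frame of [sir_test()] rows, one per group present in both
#'   the cases and the reference.
#' @export
sir_table <- function(case_counts, n_cases, reference, level = 0.95) {
  groups <- intersect(case_counts$group_name,
                      names(reference$weighted_carriers_by_group))
  rows <- lapply(groups, function(g) {
    p_ref <- reference$weighted_carriers_by_group[[g]] / reference$n_ref
    if (p_ref <= 0) return(NULL)  # expected count would be 0: SIR undefined
    obs <- case_counts$weighted_x[case_counts$group_name == g][1]
    sir_test(obs, expected_count(p_ref, n_cases), level, group_name = g)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(group_name = character(0), observed = numeric(0),
                      expected = numeric(0), sir = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
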