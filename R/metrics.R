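# Goodness-of-fit statistics and the paired nonparametric comparison test.

#' Root mean square error with parameter-count correction
#'
#' \deqn{RMSE = \sqrt{\sum_i (x_{obs,i} - x_{fit,i})^2 / (n - s)}}
#' Mechanistic fits use the number of fitted parameters for `s`; for
#' regressors without a defined parameter count use `s = 0`, which reduces
#' to the plain root mean square.
#'
#' @param observed,fitted numeric vectors of equal length.
#' @param s number of fitted parameters (default 0).
#' @return RMSE in the units of the response.
#' @export
rmse <- function(observed, fitted, s = 0) {
  check_num(observed, "observed"); check_num(fitted, "fitted", length(observed))
  n <- length(observed)
  if (n <= s) stop_pm("need more observations than parameters", "pm_domain_error")
  sqrt(sum((observed - fitted)^2) / (n - s))
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SSE/SST} with SST taken about the mean of the
#' observations.
#'
#' @inheritParams rmse
#' @return R squared (at most 1; can be negative for fits worse than the
#'   mean predictor).
#' @export
r_squared <- function(observed, fitted) {
  check_num(observed, "observed"); check_num(fitted, "fitted", length(observed))
  sse <- sum((observed - fitted)^2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop_pm("constant observations: R^2 undefined", "pm_domain_error")
  1 - sse / sst
}

#' Wilcoxon signed-rank test for paired model comparisons
#'
#' Two-sided test of the null that paired differences are symmetric about
#' zero, used to compare performance metrics of two modelling approaches
#' on the same datasets.  Zero differences are dropped before ranking
#' (Wilcoxon's original procedure) and tied absolute differences share
#' mid-ranks.  With no ties and 25 or fewer non-zero pairs the exact null
#' distribution of the signed-rank statistic is used; otherwise a normal
#' approximation with tie correction.
#'
#' @param a,b paired numeric vectors (e.g. per-dataset RMSEs of two
#'   approaches).
#' @return List with `statistic` (V, sum of ranks of positive
#'   differences), `p_value`, `n` (non-zero pairs used) and `method`.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))$p_value  # 0.0625
#' @export
wilcoxon_signed_rank <- function(a, b) {
  check_num(a, "a"); check_num(b, "b", length(a))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_pm("all paired differences are zero", "pm_degenerate_error")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= 25) {
    # exact two-sided p from the null distribution of V
    p <- 2 * min(stats::psignrank(v, n), 1 - stats::psignrank(v - 1, n))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = v, p_value = p, n = n, method = method)
}
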