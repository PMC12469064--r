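# Uncertainty quantification: Gauss-Newton parameter covariance, standard
# errors, delta-method prediction bands, and percentile-bootstrap bands.

#' Parameter covariance from a least-squares fit
#'
#' Gauss-Newton approximation \eqn{C = s^2 (J^T J)^{-1}} with the residual
#' variance \eqn{s^2 = SSE/(n - p)}.  This is the covariance a
#' Levenberg-Marquardt implementation exposes at the optimum.  If the
#' Jacobian is rank deficient the Moore-Penrose pseudo-inverse is used
#' with a warning.
#'
#' @param jacobian n x p sensitivity matrix of model predictions with
#'   respect to the parameters, evaluated at the estimates.
#' @param residuals length-n residual vector (observed - fitted).
#' @return p x p covariance matrix (symmetric, positive semi-definite).
#' @export
param_covariance <- function(jacobian, residuals) {
  jacobian <- as.matrix(jacobian)
  check_num(residuals, "residuals")
  n <- nrow(jacobian); p <- ncol(jacobian)
  if (length(residuals) != n) {
    stop_pm("residuals must match the Jacobian's row count", "pm_domain_error")
  }
  if (n <= p) stop_pm("need more observations than parameters", "pm_domain_error")
  s2 <- sum(residuals^2) / (n - p)
  jtj <- crossprod(jacobian)
  if (qr(jtj)$rank < p) {
    warning("rank-deficient Jacobian: using pseudo-inverse covariance")
    cv <- s2 * MASS::ginv(jtj)
  } else {
    cv <- s2 * chol2inv(chol(jtj))
  }
  cv <- (cv + t(cv)) / 2
  dimnames(cv) <- list(colnames(jacobian), colnames(jacobian))
  cv
}

#' Per-parameter standard errors
#'
#' @param covariance parameter covariance matrix.
#' @return Square roots of the diagonal.
#' @export
standard_errors <- function(covariance) {
  covariance <- as.matrix(covariance)
  sqrt(pmax(diag(covariance), 0))
}

#' @noRd
new_band <- function(times, mean, sigma, lower, upper, method) {
  structure(list(times = times, mean = mean, sigma = sigma,
                 lower = lower, upper = upper, method = method),
            class = "pm_band")
}

#' @export
as.data.frame.pm_band <- function(x, ...) {
  data.frame(time = x$times, mean = x$mean, sigma = x$sigma,
             lower = x$lower, upper = x$upper)
}

#' @export
print.pm_band <- function(x, ...) {
  cat(sprintf("<pm_band> %s, %d points, mean half-width %.4g\n",
              x$method, length(x$times), mean(x$upper - x$mean)))
  invisible(x)
}

#' Delta-method 95% prediction band
#'
#' Pointwise prediction variance
#' \eqn{\sigma^2_{\hat y}(t) = \nabla f(t,\hat\theta)^T C \nabla f(t,\hat\theta) + s^2}
#' with bounds \eqn{\hat y \pm 1.96\,\sigma_{\hat y}}.  The gradient with
#' respect to the parameters is obtained by central finite differences
#' (relative step 1e-6) unless `grad_fn` supplies it analytically.
#'
#' @param fn model function `fn(times, params)` returning predictions.
#' @param params named numeric vector of parameter estimates.
#' @param covariance parameter covariance matrix C.
#' @param s2 residual variance.
#' @param times evaluation grid.
#' @param grad_fn optional `function(times, params)` returning the n x p
#'   gradient matrix.
#' @return A `pm_band` object with fields `times`, `mean`, `sigma`,
#'   `lower`, `upper`.
#' @export
prediction_band <- function(fn, params, covariance, s2, times,
                            grad_fn = NULL) {
  check_num(times, "times"); check_num(s2, "s2", 1)
  covariance <- as.matrix(covariance)
  mean_pred <- fn(times, params)
  if (is.null(grad_fn)) {
    G <- numeric_jacobian(function(p) fn(times, p), params)
  } else {
    G <- grad_fn(times, params)
  }
  var_pred <- rowSums((G %*% covariance) * G) + s2
  sigma <- sqrt(pmax(var_pred, 0))
  new_band(times, mean_pred, sigma,
           mean_pred - 1.96 * sigma, mean_pred + 1.96 * sigma,
           method = "delta")
}

#' Non-parametric percentile bootstrap 95% band
#'
#' Resamples the rows of `train_data` with replacement `B` times, refits
#' with `train_fn`, predicts at `query_points`, and takes the empirical
#' 2.5th/97.5th percentiles of the aggregated predictions as the interval
#' bounds; the band mean is the average bootstrap prediction.  Bitwise
#' reproducible for a fixed `seed`.
#'
#' @param train_fn `function(data)` returning a prediction function
#'   `function(query_points) -> numeric`; must be deterministic given its
#'   data (seed any internal randomness from the enclosing environment).
#' @param train_data data frame of training rows to resample.
#' @param query_points points at which to predict (passed unchanged to
#'   the fitted prediction function).
#' @param B number of bootstrap iterations (default 100).
#' @param seed RNG seed.
#' @return A `pm_band` object (sigma is the bootstrap standard deviation).
#' @export
bootstrap_band <- function(train_fn, train_data, query_points, B = 100,
                           seed = 20250910) {
  if (B < 2) stop_pm("B must be at least 2", "pm_domain_error")
  n <- nrow(train_data)
  nq <- nq_len(query_points)
  preds <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    out <- matrix(NA_real_, nrow = B, ncol = nq)
    for (b in seq_len(B)) {
      fit <- train_fn(train_data[idx[b, ], , drop = FALSE])
      out[b, ] <- as.numeric(fit(query_points))
    }
    out
  })
  mean_pred <- colMeans(preds)
  lower <- apply(preds, 2, stats::quantile, probs = 0.025, names = FALSE)
  upper <- apply(preds, 2, stats::quantile, probs = 0.975, names = FALSE)
  sigma <- apply(preds, 2, stats::sd)
  new_band(query_times(query_points), mean_pred, sigma, lower, upper,
           method = "bootstrap")
}

# Query points may be a numeric grid or a data frame of features.
nq_len <- function(q) if (is.data.frame(q) || is.matrix(q)) nrow(q) else length(q)
query_times <- function(q) {
  if (is.data.frame(q)) q[[1]] else if (is.matrix(q)) q[, 1] else q
}
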