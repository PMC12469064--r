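# Gaussian process regression with a squared-exponential kernel plus
# additive white noise.  Hyperparameters (signal sd, length scale, noise
# sd) are chosen by marginal-likelihood maximisation with seeded
# restarts; the analytic gradient of the log marginal likelihood keeps
# the optimisation cheap enough for augmented training sets.

#' @noRd
sq_dist <- function(A, B = A) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

# negative log marginal likelihood and its gradient wrt
# theta = (log sigma_f, log ell, log sigma_n)
#' @noRd
gpr_nll <- function(theta, D2, y, jitter = 1e-8) {
  sf2 <- exp(2 * theta[1]); ell2 <- exp(2 * theta[2]); sn2 <- exp(2 * theta[3])
  n <- length(y)
  Kse <- sf2 * exp(-D2 / (2 * ell2))
  K <- Kse + diag(sn2 + jitter, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(list(value = 1e10, grad = rep(0, 3)))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(L)
  A <- tcrossprod(alpha) - Kinv              # d(logML)/dK = A/2
  g_sf <- -0.5 * sum(A * (2 * Kse))          # dK/d(log sf) = 2 Kse
  g_ell <- -0.5 * sum(A * (Kse * (D2 / ell2)))
  g_sn <- -0.5 * sum(diag(A)) * 2 * sn2
  list(value = nll, grad = c(g_sf, g_ell, g_sn))
}

#' Fit a Gaussian process regressor
#'
#' Squared-exponential (RBF) kernel with an additive white-noise term:
#' \eqn{k(x, x') = \sigma_f^2 \exp(-\|x-x'\|^2 / 2\ell^2) + \sigma_n^2 \delta_{xx'}}.
#' Hyperparameters are estimated by maximising the log marginal
#' likelihood (L-BFGS-B with analytic gradients) from `restarts` seeded
#' starting points around data-driven scales.
#'
#' @param X numeric matrix of (scaled) features.
#' @param y numeric response.
#' @param restarts number of seeded optimiser restarts (default 5).
#' @param seed RNG seed for the restarts.
#' @param maxit optimiser iteration cap per restart.
#' @return An object of class `pm_gpr`.
#' @export
gpr_fit <- function(X, y, restarts = 5, seed = DEFAULT_SEED, maxit = 60) {
  X <- as.matrix(X)
  n <- nrow(X)
  ym <- mean(y)
  yc <- y - ym
  D2 <- sq_dist(X)
  sy <- stats::sd(y); if (!is.finite(sy) || sy == 0) sy <- 1
  med <- stats::median(sqrt(D2[upper.tri(D2)]))
  if (!is.finite(med) || med == 0) med <- 1
  base <- log(c(sy, med, 0.1 * sy))
  lowerb <- log(c(1e-4 * sy, 1e-3 * med, 1e-4 * sy))
  upperb <- log(c(1e3 * sy, 1e3 * med, 10 * sy))
  starts <- with_seed(seed, {
    c(list(base), lapply(seq_len(max(restarts - 1, 0)), function(i) {
      pmin(pmax(base + stats::rnorm(3, 0, 1), lowerb), upperb)
    }))
  })
  best <- NULL
  # optim calls fn and gr at the same point back to back: cache one evaluation
  cache <- new.env(parent = emptyenv())
  nll_at <- function(th) {
    key <- paste(format(th, digits = 17), collapse = ",")
    if (!identical(cache$key, key)) {
      cache$key <- key
      cache$val <- gpr_nll(th, D2, yc)
    }
    cache$val
  }
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st,
                   fn = function(th) nll_at(th)$value,
                   gr = function(th) nll_at(th)$grad,
                   method = "L-BFGS-B", lower = lowerb, upper = upperb,
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop_pm("GPR hyperparameter optimisation failed",
                             "pm_convergence_error")
  th <- best$par
  sf2 <- exp(2 * th[1]); ell2 <- exp(2 * th[2]); sn2 <- exp(2 * th[3])
  K <- sf2 * exp(-D2 / (2 * ell2)) + diag(sn2 + 1e-8, n)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  structure(list(X = X, y_mean = ym, alpha = alpha, L = L,
                 sigma_f2 = sf2, ell2 = ell2, sigma_n2 = sn2,
                 nll = best$value),
            class = "pm_gpr")
}

#' Predict from a fitted Gaussian process
#'
#' @param object a `pm_gpr` fit.
#' @param newdata matrix of features at which to predict.
#' @param se return the predictive standard deviation as well (includes
#'   the noise variance, i.e. a prediction rather than confidence scale).
#' @param ... unused.
#' @return Numeric vector of means, or a list `(mean, sd)` when
#'   `se = TRUE`.
#' @export
predict.pm_gpr <- function(object, newdata, se = FALSE, ...) {
  Xs <- as.matrix(newdata)
  Ks <- object$sigma_f2 * exp(-sq_dist(Xs, object$X) / (2 * object$ell2))
  mu <- as.numeric(Ks %*% object$alpha) + object$y_mean
  if (!se) return(mu)
  v <- forwardsolve(t(object$L), t(Ks))
  var <- object$sigma_f2 + object$sigma_n2 - colSums(v^2)
  list(mean = mu, sd = sqrt(pmax(var, 0)))
}

#' @export
print.pm_gpr <- function(x, ...) {
  cat(sprintf(
    "<pm_gpr> n = %d, sigma_f = %.4g, length scale = %.4g, sigma_n = %.4g\n",
    nrow(x$X), sqrt(x$sigma_f2), sqrt(x$ell2), sqrt(x$sigma_n2)))
  invisible(x)
}
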