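# Primary-model fitting: seeded multi-start Levenberg-Marquardt least
# squares with data-driven initial values and box constraints.

DEFAULT_SEED <- 20250910

#' @noRd
nls_multistart <- function(resid_fn, starts, lower, upper,
                           maxiter = 500) {
  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                     gtol = 0, maxiter = maxiter)
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- fit$deviance
    if (is.null(best) || sse < best$deviance - 1e-12 ||
        (abs(sse - best$deviance) <= 1e-12 &&
         sum(unlist(fit$par)^2) < sum(unlist(best$par)^2))) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop_pm("nonlinear least squares failed to converge from any start",
            "pm_convergence_error")
  }
  best
}

#' @noRd
jitter_starts <- function(base, n_starts, seed, lower, upper) {
  with_seed(seed, {
    starts <- list(base)
    for (i in seq_len(n_starts - 1)) {
      s <- base * exp(stats::rnorm(length(base), 0, 0.3))
      # additive jitter for parameters that may be near zero or negative
      shift <- stats::rnorm(length(base), 0, 0.25 * pmax(abs(base), 0.5))
      s <- ifelse(base > 0, s, base + shift)
      starts[[i + 1]] <- pmin(pmax(s, lower), upper)
    }
    starts
  })
}

# Slope of the steepest 3-point moving secant; returns list(rate, t_at, y_at).
#' @noRd
max_secant <- function(times, values) {
  n <- length(times)
  if (n < 3) {
    sl <- (values[n] - values[1]) / (times[n] - times[1])
    return(list(rate = sl, t_at = mean(times), y_at = mean(values)))
  }
  sl <- (values[3:n] - values[1:(n - 2)]) / (times[3:n] - times[1:(n - 2)])
  i <- which.max(sl)   # steepest rise; noise near the plateau can produce
                       # larger-magnitude negative secants, so not abs()
  list(rate = sl[i], t_at = times[i + 1], y_at = values[i + 1])
}

#' Fit a primary growth model to one curve
#'
#' Estimates the four kinetic parameters of the chosen sigmoid by
#' least squares, using a seeded multi-start around data-driven initial
#' values (first observation for `x0`, maximum for `xmax`, steepest
#' 3-point secant for the rate, tangent intercept for the lag).
#' For the Baranyi and Huang models the rate is reported directly as
#' `mumax` (1/h); for modified Gompertz and Logistic the log10-scale
#' `rmax` is estimated and `mumax = rmax * ln 10` is attached as a
#' derived quantity, so every model reports a specific growth rate on
#' the same scale.
#'
#' @param curve a [pm_curve()] (times in h, response in log10 CFU/g).
#' @param model_id `"gompertz"`, `"logistic"`, `"baranyi"` or `"huang"`.
#' @param seed RNG seed for the multi-start jitter.
#' @param n_starts number of starts (>= 1; default 8).
#' @return A `pm_fit` with estimates, standard errors, covariance,
#'   residual variance, RMSE and R2.
#' @export
fit_primary_growth <- function(curve, model_id = GROWTH_MODELS,
                               seed = DEFAULT_SEED, n_starts = 8) {
  model_id <- match.arg(model_id)
  stopifnot(inherits(curve, "pm_curve"))
  tt <- curve$times; yy <- curve$values
  if (length(tt) < 5) {
    stop_pm("growth fitting needs at least 5 observations", "pm_data_error")
  }
  span <- max(yy) - min(yy)
  if (span <= 1) {
    stop_pm("observed range spans less than one log10 unit: no growth to fit",
            "pm_data_error")
  }
  sec <- max_secant(tt, yy)
  if (stats::cor(tt, yy) < 0 || sec$rate <= 0) {
    stop_pm("data decline over time: not a growth curve", "pm_data_error")
  }
  x0h <- min(yy[1], yy[2])
  xmaxh <- max(yy)
  rh <- max(sec$rate, 1e-3)            # log10 / h
  lagh <- max(sec$t_at - (sec$y_at - x0h) / rh, 0)
  ln_scale <- model_id %in% c("baranyi", "huang")
  rate_h <- if (ln_scale) rmax_to_mumax(rh) else rh
  base <- c(x0 = x0h, xmax = xmaxh, rate = rate_h, lag = lagh)
  lower <- c(min(yy) - 5, max(yy) - 2, 1e-6, 0)
  upper <- c(min(yy) + 2, max(yy) + 5, 50 * rate_h + 1, max(tt))
  rate_name <- if (ln_scale) "mumax" else "rmax"
  model_fn <- function(t, par) {
    p <- stats::setNames(as.numeric(par), c("x0", "xmax", rate_name, "lag"))
    eval_primary_safe(model_id, t, p)
  }
  resid_fn <- function(par) yy - model_fn(tt, par)
  starts <- jitter_starts(base, n_starts, seed, lower, upper)
  best <- nls_multistart(resid_fn, starts, lower, upper)
  est <- stats::setNames(as.numeric(best$par), c("x0", "xmax", rate_name, "lag"))
  fitted_vals <- model_fn(tt, est)
  res <- yy - fitted_vals
  J <- numeric_jacobian(function(p) model_fn(tt, p), est)
  derived <- if (ln_scale) {
    list(rmax = mumax_to_rmax(est[["mumax"]]))
  } else {
    list(mumax = rmax_to_mumax(est[["rmax"]]))
  }
  new_fit_result(model_id, est, res, yy, fitted_vals, J, derived,
                 extra = list(times = tt, condition = curve$condition,
                              kind = "growth"))
}

#' Fit a primary inactivation model to one curve
#'
#' Least-squares estimation of the Log-Linear, Log-Linear + Tail or
#' Weibull survival-curve parameters with a seeded multi-start.  Initial
#' values: first observation for `logN0`, interpolated time of the first
#' 1-log drop for `delta`, shape `p = 1`, overall slope for `k`, minimum
#' observation for the tail.
#'
#' @param curve a [pm_curve()] (times in s, response in log10).
#' @param model_id `"loglinear"`, `"loglinear_tail"` or `"weibull"`.
#' @inheritParams fit_primary_growth
#' @return A `pm_fit`.
#' @export
fit_primary_inhibition <- function(curve, model_id = INACT_MODELS,
                                   seed = DEFAULT_SEED, n_starts = 8) {
  model_id <- match.arg(model_id)
  stopifnot(inherits(curve, "pm_curve"))
  tt <- curve$times; yy <- curve$values
  if (length(tt) < 4) {
    stop_pm("inactivation fitting needs at least 4 observations", "pm_data_error")
  }
  if (stats::cor(tt, yy) > 0) {
    stop_pm("data increase over time: not an inactivation curve", "pm_data_error")
  }
  n0h <- yy[1]
  drop_total <- n0h - min(yy)
  kh <- max((n0h - yy[length(yy)]) / max(tt), 1e-6)
  # time of first observed 1-log drop, linearly interpolated
  deltah <- if (drop_total >= 1) {
    stats::approx(n0h - yy, tt, xout = 1, ties = mean)$y
  } else {
    max(tt) / 2
  }
  deltah <- max(deltah, min(tt[tt > 0]), na.rm = TRUE)
  names_ <- inact_param_names(model_id)
  base <- switch(model_id,
    loglinear = c(logN0 = n0h, k = kh),
    loglinear_tail = c(logN0 = n0h, k = 2 * kh, logNres = min(yy)),
    weibull = c(logN0 = n0h, delta = deltah, p = 1)
  )
  lower <- switch(model_id,
    loglinear = c(n0h - 3, 0),
    loglinear_tail = c(n0h - 3, 1e-6, min(yy) - 3),
    weibull = c(n0h - 3, 1e-3, 0.05)
  )
  upper <- switch(model_id,
    loglinear = c(n0h + 3, 100 * kh + 1),
    loglinear_tail = c(n0h + 3, 1e3 * kh + 1, n0h - 0.1),
    weibull = c(n0h + 3, 10 * max(tt), 5)
  )
  model_fn <- function(t, par) {
    eval_primary_safe(model_id, t, stats::setNames(as.numeric(par), names_))
  }
  resid_fn <- function(par) yy - model_fn(tt, par)
  starts <- jitter_starts(base, n_starts, seed, lower, upper)
  best <- nls_multistart(resid_fn, starts, lower, upper)
  est <- stats::setNames(as.numeric(best$par), names_)
  fitted_vals <- model_fn(tt, est)
  res <- yy - fitted_vals
  J <- numeric_jacobian(function(p) model_fn(tt, p), est)
  new_fit_result(model_id, est, res, yy, fitted_vals, J,
                 extra = list(times = tt, condition = curve$condition,
                              kind = "inhibition"))
}

#' Delta-method prediction band for a fitted primary model
#'
#' Convenience wrapper joining a `pm_fit` from [fit_primary_growth()] or
#' [fit_primary_inhibition()] with [prediction_band()].
#'
#' @param fit a `pm_fit` for a primary model.
#' @param times evaluation grid (defaults to 100 points over the data range).
#' @return A `pm_band`.
#' @export
primary_band <- function(fit, times = NULL) {
  stopifnot(inherits(fit, "pm_fit"))
  if (is.null(times)) times <- seq(min(fit$times), max(fit$times), length.out = 100)
  fn <- function(t, par) eval_primary(fit$model_id, t, par)
  prediction_band(fn, fit$estimates, fit$covariance, fit$resid_var, times)
}
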