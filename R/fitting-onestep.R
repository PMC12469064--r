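# One-step (global) fitting: the secondary model is substituted into the
# primary equation and all parameters are estimated simultaneously over
# every curve, minimising the joint SSE.

#' @noRd
stack_dataset <- function(dataset) {
  df <- as.data.frame(dataset)
  list(times = df$time, values = df$response, conds = df$condition)
}

#' One-step global fit of a growth dataset
#'
#' Shares a single parameter vector `(x0, xmax, xmin, b1, b2)` across all
#' curves: for a curve at condition X the specific rate is
#' `mumax(X) = b1 * (X - xmin)^2`, the lag `lag(X) = b2 / mumax(X)`, and
#' those are substituted into the chosen primary model (with
#' `rmax = mumax / ln 10` for the log10-scale models).  The joint SSE over
#' every observation is minimised by seeded multi-start
#' Levenberg-Marquardt.  Starts are built from per-curve secant
#' heuristics: a straight line through `sqrt(mu)` versus X seeds
#' `(b1, xmin)` and the per-curve lag heuristics seed `b2`.
#'
#' @param dataset a [pm_dataset()] of kind `"growth"` with >= 2 distinct
#'   conditions, each curve with >= 5 observations.
#' @param model_id `"gompertz"`, `"logistic"`, `"baranyi"` or `"huang"`.
#' @param seed RNG seed.
#' @param n_starts multi-start count (default 8).
#' @return A `pm_fit` with the five global estimates.  A rank-deficient
#'   Jacobian at the optimum triggers a warning and a pseudo-inverse
#'   covariance.
#' @export
fit_one_step_growth <- function(dataset, model_id = GROWTH_MODELS,
                                seed = DEFAULT_SEED, n_starts = 8) {
  model_id <- match.arg(model_id)
  stopifnot(inherits(dataset, "pm_dataset"), dataset$kind == "growth")
  conds <- dataset_conditions(dataset)
  if (length(unique(conds)) < 2) {
    stop_pm("one-step fitting needs at least 2 distinct conditions",
            "pm_data_error")
  }
  if (any(vapply(dataset$curves, function(cv) length(cv$times), 0L) < 5)) {
    stop_pm("every curve needs at least 5 observations", "pm_data_error")
  }
  st <- stack_dataset(dataset)
  ln_scale <- model_id %in% c("baranyi", "huang")

  # per-curve heuristics feed the global starts
  per <- lapply(dataset$curves, function(cv) {
    sec <- max_secant(cv$times, cv$values)
    r <- max(sec$rate, 1e-4) * LN10          # specific rate, 1/h
    x0h <- min(cv$values[1], cv$values[2])
    lagh <- max(sec$t_at - (sec$y_at - x0h) / (r / LN10), 0)
    c(mu = r, lag = lagh, x0 = x0h)
  })
  mu_h <- vapply(per, `[[`, 0, "mu")
  lag_h <- vapply(per, `[[`, 0, "lag")
  uc <- unique(conds)
  mu_by_cond <- vapply(uc, function(x) mean(mu_h[conds == x]), 0)
  ln0 <- stats::lm(sqrt(mu_by_cond) ~ uc)
  slope <- stats::coef(ln0)[[2]]
  xminh <- if (slope > 0) -stats::coef(ln0)[[1]] / slope else min(conds) - 10
  xminh <- min(xminh, min(conds) - 0.5)
  b1h <- max(stats::median(mu_h / (conds - xminh)^2), 1e-8)
  b2h <- max(stats::median(lag_h * mu_h), 0)
  base <- c(x0 = mean(vapply(per, `[[`, 0, "x0")),
            xmax = max(st$values), xmin = xminh, b1 = b1h, b2 = b2h)
  lower <- c(min(st$values) - 5, max(st$values) - 2, min(conds) - 60, 1e-10, 0)
  upper <- c(min(st$values) + 3, max(st$values) + 5, min(conds) - 1e-3, 1, 100)

  model_fn <- function(par) {
    x0 <- par[[1]]; xmax <- par[[2]]; xmin <- par[[3]]
    b1 <- max(par[[4]], 1e-10); b2 <- max(par[[5]], 0)
    mu <- b1 * pmax(st$conds - xmin, 1e-3)^2
    lag <- b2 / mu
    out <- numeric(length(st$times))
    for (x in unique(st$conds)) {
      i <- st$conds == x
      mu_x <- mu[i][1]; lag_x <- lag[i][1]
      pars <- if (ln_scale) {
        c(x0 = x0, xmax = xmax, mumax = mu_x, lag = lag_x)
      } else {
        c(x0 = x0, xmax = xmax, rmax = mu_x / LN10, lag = lag_x)
      }
      out[i] <- eval_primary_safe(model_id, st$times[i], pars)
    }
    out
  }
  resid_fn <- function(par) st$values - model_fn(par)
  starts <- jitter_starts(base, n_starts, seed, lower, upper)
  best <- nls_multistart(resid_fn, starts, lower, upper)
  est <- stats::setNames(as.numeric(best$par),
                         c("x0", "xmax", "xmin", "b1", "b2"))
  fitted_vals <- model_fn(est)
  res <- st$values - fitted_vals
  J <- numeric_jacobian(function(p) model_fn(p), est)
  new_fit_result(paste0(model_id, "_one_step"), est, res, st$values,
                 fitted_vals, J,
                 extra = list(times = st$times, conditions = st$conds,
                              kind = "growth", primary_model = model_id))
}

#' One-step global fit of an inactivation dataset
#'
#' For the Weibull model the shared parameters are
#' `(logN0, a, b, p)` with `delta(X) = a - b * log10(X)` substituted for
#' the first-decimal-reduction time; the Log-Linear variants substitute
#' `k(X) = a - b * log10(X)` instead (adding `logNres` for the tail
#' model).  A soft penalty keeps the substituted delta or k positive over
#' the fitted condition range.
#'
#' @param dataset a [pm_dataset()] of kind `"inhibition"` with >= 2
#'   distinct conditions.
#' @param model_id `"loglinear"`, `"loglinear_tail"` or `"weibull"`.
#' @inheritParams fit_one_step_growth
#' @return A `pm_fit` with the shared global estimates.
#' @export
fit_one_step_inhibition <- function(dataset, model_id = INACT_MODELS,
                                    seed = DEFAULT_SEED, n_starts = 8) {
  model_id <- match.arg(model_id)
  stopifnot(inherits(dataset, "pm_dataset"), dataset$kind == "inhibition")
  conds <- dataset_conditions(dataset)
  if (length(unique(conds)) < 2) {
    stop_pm("one-step fitting needs at least 2 distinct conditions",
            "pm_data_error")
  }
  st <- stack_dataset(dataset)
  lx_all <- log10(st$conds)
  uc <- unique(conds)

  # per-curve heuristic for the kinetic parameter, then a line on log10(X)
  per_val <- vapply(dataset$curves, function(cv) {
    n0h <- cv$values[1]
    drop <- n0h - cv$values
    if (model_id == "weibull") {
      if (max(drop) >= 1) stats::approx(drop, cv$times, xout = 1,
                                        ties = mean)$y
      else max(cv$times) / 2
    } else {
      max((n0h - cv$values[length(cv$values)]) / max(cv$times), 1e-6)
    }
  }, 0)
  ln0 <- stats::lm(per_val ~ log10(conds))
  ah <- stats::coef(ln0)[[1]]
  bh <- -stats::coef(ln0)[[2]]
  n0h <- mean(vapply(dataset$curves, function(cv) cv$values[1], 0))
  names_ <- switch(model_id,
    loglinear = c("logN0", "a", "b"),
    loglinear_tail = c("logN0", "logNres", "a", "b"),
    weibull = c("logN0", "a", "b", "p")
  )
  base <- switch(model_id,
    loglinear = c(logN0 = n0h, a = ah, b = bh),
    loglinear_tail = c(logN0 = n0h, logNres = min(st$values),
                       a = ah, b = bh),
    weibull = c(logN0 = n0h, a = ah, b = bh, p = 1)
  )
  big <- 10 * max(abs(c(ah, bh, 1)))
  lower <- switch(model_id,
    loglinear = c(n0h - 3, -big, -big),
    loglinear_tail = c(n0h - 3, min(st$values) - 3, -big, -big),
    weibull = c(n0h - 3, -big, -big, 0.05)
  )
  upper <- switch(model_id,
    loglinear = c(n0h + 3, big, big),
    loglinear_tail = c(n0h + 3, n0h - 0.1, big, big),
    weibull = c(n0h + 3, big, big, 5)
  )
  n_pen <- length(uc)
  model_fn <- function(par) {
    par <- stats::setNames(as.numeric(par), names_)
    kin <- par[["a"]] - par[["b"]] * lx_all
    kin_pos <- pmax(kin, 1e-4)
    out <- numeric(length(st$times))
    for (x in uc) {
      i <- st$conds == x
      pars <- switch(model_id,
        loglinear = c(logN0 = par[["logN0"]], k = kin_pos[i][1]),
        loglinear_tail = c(logN0 = par[["logN0"]], k = kin_pos[i][1],
                           logNres = par[["logNres"]]),
        weibull = c(logN0 = par[["logN0"]], delta = kin_pos[i][1],
                    p = par[["p"]])
      )
      out[i] <- eval_primary_safe(model_id, st$times[i], pars)
    }
    out
  }
  resid_fn <- function(par) {
    par <- stats::setNames(as.numeric(par), names_)
    kin_u <- par[["a"]] - par[["b"]] * log10(uc)
    pen <- 50 * pmax(1e-4 - kin_u, 0)      # keep delta/k positive per condition
    c(st$values - model_fn(par), pen)
  }
  starts <- jitter_starts(base, n_starts, seed, lower, upper)
  best <- nls_multistart(resid_fn, starts, lower, upper)
  est <- stats::setNames(as.numeric(best$par), names_)
  fitted_vals <- model_fn(est)
  res <- st$values - fitted_vals
  J <- numeric_jacobian(function(p) model_fn(p), est)
  new_fit_result(paste0(model_id, "_one_step"), est, res, st$values,
                 fitted_vals, J,
                 extra = list(times = st$times, conditions = st$conds,
                              kind = "inhibition", primary_model = model_id))
}

#' Joint SSE of a dataset under a global growth parameter vector
#'
#' Evaluates the one-step growth model at a given parameter vector and
#' returns the joint sum of squared errors, e.g. to compare the one-step
#' optimum against a two-step reconstruction frozen into the global
#' parameterisation.
#'
#' @param dataset a growth [pm_dataset()].
#' @param model_id primary model identifier.
#' @param params named vector `(x0, xmax, xmin, b1, b2)`.
#' @return The joint SSE.
#' @export
one_step_growth_sse <- function(dataset, model_id, params) {
  st <- stack_dataset(dataset)
  ln_scale <- model_id %in% c("baranyi", "huang")
  out <- numeric(length(st$times))
  for (x in unique(st$conds)) {
    i <- st$conds == x
    mu <- ratkowsky_mu(x, params[["b1"]], params[["xmin"]])
    lag <- if (mu > 0) params[["b2"]] / mu else 0
    pars <- if (ln_scale) {
      c(x0 = params[["x0"]], xmax = params[["xmax"]], mumax = mu, lag = lag)
    } else {
      c(x0 = params[["x0"]], xmax = params[["xmax"]],
        rmax = mu / LN10, lag = lag)
    }
    out[i] <- eval_primary_safe(model_id, st$times[i], pars)
  }
  sum((st$values - out)^2)
}
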