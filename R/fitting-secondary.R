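# Secondary-model fitting and the two-step workflow.

#' Fit the growth secondary model to per-condition kinetic estimates
#'
#' Estimates `(b1, xmin)` by nonlinear least squares of
#' `mumax = b1 * (X - xmin)^2` on the per-condition rate estimates, and
#' `b2` by least squares of `lag = b2 / mumax` (closed form, regression
#' through the origin of `lag` on `1/mumax`).  The covariance of
#' `(b1, xmin)` and the variance of `b2` are assembled block-diagonally
#' since the two regressions use independent responses.
#'
#' @param param_table data frame with columns `condition`, `mumax` and
#'   optionally `lag` (>= 3 rows).
#' @param seed RNG seed for the multi-start jitter.
#' @param n_starts number of starts.
#' @return A `pm_fit` with estimates `b1`, `xmin` and (when lags are
#'   supplied) `b2`.
#' @export
fit_secondary_growth <- function(param_table, seed = DEFAULT_SEED,
                                 n_starts = 8) {
  stopifnot(is.data.frame(param_table),
            all(c("condition", "mumax") %in% names(param_table)))
  X <- param_table$condition
  mu <- param_table$mumax
  if (length(unique(X)) < 3) {
    stop_pm("secondary growth fitting needs at least 3 distinct conditions",
            "pm_data_error")
  }
  # sqrt(mu) is linear in X under the model: seed (b1, xmin) from that line
  sq <- sqrt(pmax(mu, 0))
  ln <- stats::lm(sq ~ X)
  slope <- stats::coef(ln)[[2]]
  xminh <- if (slope > 0) -stats::coef(ln)[[1]] / slope else min(X) - 5
  xminh <- min(xminh, min(X) - 0.5)
  b1h <- max(mean(mu / (X - xminh)^2), 1e-8)
  base <- c(b1 = b1h, xmin = xminh)
  lower <- c(1e-10, min(X) - 60)
  upper <- c(1, min(X) - 1e-3)
  resid_fn <- function(par) mu - par[[1]] * (X - par[[2]])^2
  starts <- jitter_starts(base, n_starts, seed, lower, upper)
  best <- nls_multistart(resid_fn, starts, lower, upper)
  est <- stats::setNames(as.numeric(best$par), c("b1", "xmin"))
  have_lag <- "lag" %in% names(param_table) && !anyNA(param_table$lag)
  fitted_mu <- est[["b1"]] * (X - est[["xmin"]])^2
  res_mu <- mu - fitted_mu
  J <- numeric_jacobian(function(p) p[[1]] * (X - p[[2]])^2, est)
  if (have_lag) {
    lagv <- param_table$lag
    w <- 1 / mu
    b2 <- sum(lagv * w) / sum(w^2)
    res_lag <- lagv - b2 * w
    # regression-through-origin variance for b2
    df_lag <- max(length(lagv) - 1, 1)
    var_b2 <- sum(res_lag^2) / df_lag / sum(w^2)
    est <- c(est, b2 = b2)
    cv2 <- param_covariance(J, res_mu)
    cv <- rbind(cbind(cv2, 0), 0)
    cv[3, 3] <- var_b2
    dimnames(cv) <- list(names(est), names(est))
    observed <- c(mu, lagv)
    fitted_all <- c(fitted_mu, b2 * w)
    residuals_all <- observed - fitted_all
    se <- standard_errors(cv); names(se) <- names(est)
    out <- structure(list(
      model_id = "ratkowsky",
      estimates = est, std_errors = se, covariance = cv,
      resid_var = sum(res_mu^2) / (length(mu) - 2),
      n_obs = length(observed), n_params = 3,
      rmse = rmse(mu, fitted_mu, s = 2),
      r2 = r_squared(mu, fitted_mu),
      sse = sum(res_mu^2),
      sst = sum((mu - mean(mu))^2),
      fitted = fitted_all, residuals = residuals_all,
      derived = list(), param_table = param_table, kind = "growth"
    ), class = "pm_fit")
    return(out)
  }
  new_fit_result("ratkowsky", est, res_mu, mu, fitted_mu, J,
                 extra = list(param_table = param_table, kind = "growth"))
}

#' Fit the inactivation secondary model
#'
#' Linear regression of the kinetic parameter (delta or k) on log10 of
#' the environmental variable, `value = a - b * log10(X)`.
#'
#' @param param_table data frame with columns `condition` and `value`
#'   (per-condition delta or k estimates).
#' @return A `pm_fit` with estimates `a` and `b`.
#' @export
fit_secondary_inhibition <- function(param_table) {
  stopifnot(is.data.frame(param_table),
            all(c("condition", "value") %in% names(param_table)))
  if (length(unique(param_table$condition)) < 2) {
    stop_pm("secondary inactivation fitting needs at least 2 distinct conditions",
            "pm_data_error")
  }
  lx <- log10(param_table$condition)
  v <- param_table$value
  lmfit <- stats::lm(v ~ lx)
  a <- stats::coef(lmfit)[[1]]
  b <- -stats::coef(lmfit)[[2]]
  # summary.lm warns on exact (zero-residual) input; the zero covariance
  # it returns is what we want there
  cv <- suppressWarnings(stats::vcov(lmfit))  # slope sign flip keeps variances
  cv[1, 2] <- cv[2, 1] <- -cv[1, 2]
  dimnames(cv) <- list(c("a", "b"), c("a", "b"))
  est <- c(a = a, b = b)
  fitted_vals <- a - b * lx
  res <- v - fitted_vals
  se <- standard_errors(cv); names(se) <- names(est)
  n <- length(v)
  structure(list(
    model_id = "log_secondary",
    estimates = est, std_errors = se, covariance = cv,
    resid_var = sum(res^2) / max(n - 2, 1),
    n_obs = n, n_params = 2,
    rmse = if (n > 2) rmse(v, fitted_vals, s = 2) else NA_real_,
    r2 = if (n > 2) r_squared(v, fitted_vals) else NA_real_,
    sse = sum(res^2), sst = sum((v - mean(v))^2),
    fitted = fitted_vals, residuals = res,
    derived = list(), param_table = param_table, kind = "inhibition"
  ), class = "pm_fit")
}

#' Two-step estimation: primary fits per condition, then secondary
#'
#' Runs [fit_primary_growth()] or [fit_primary_inhibition()] on every
#' curve, collects the per-condition kinetic estimates, and regresses
#' them on the environmental variable with the matching secondary model.
#' For growth the secondary stage consumes `(mumax, lag)`; for
#' inactivation it consumes `delta` (Weibull) or `k` (Log-Linear
#' variants).
#'
#' @param dataset a [pm_dataset()] with at least 2 distinct conditions
#'   (3 for growth).
#' @param model_id primary model identifier.
#' @param seed RNG seed.
#' @param n_starts multi-start count for each primary fit.
#' @return A `pm_two_step` list with `primary_fits` (named by condition),
#'   `param_table` and `secondary_fit`.
#' @export
fit_two_step <- function(dataset, model_id, seed = DEFAULT_SEED,
                         n_starts = 8) {
  stopifnot(inherits(dataset, "pm_dataset"))
  conds <- dataset_conditions(dataset)
  if (length(unique(conds)) < 2) {
    stop_pm("two-step fitting needs at least 2 distinct conditions",
            "pm_data_error")
  }
  if (dataset$kind == "growth") {
    primary <- lapply(dataset$curves, fit_primary_growth, model_id = model_id,
                      seed = seed, n_starts = n_starts)
    mumax <- vapply(primary, function(f) {
      if ("mumax" %in% names(f$estimates)) f$estimates[["mumax"]]
      else f$derived$mumax
    }, 0)
    tab <- data.frame(condition = conds, mumax = mumax,
                      lag = vapply(primary, function(f) f$estimates[["lag"]], 0))
    secondary <- fit_secondary_growth(tab, seed = seed, n_starts = n_starts)
  } else {
    primary <- lapply(dataset$curves, fit_primary_inhibition,
                      model_id = model_id, seed = seed, n_starts = n_starts)
    key <- if (model_id == "weibull") "delta" else "k"
    tab <- data.frame(condition = conds,
                      value = vapply(primary, function(f) f$estimates[[key]], 0))
    if (model_id == "weibull") {
      tab$p <- vapply(primary, function(f) f$estimates[["p"]], 0)
    }
    secondary <- fit_secondary_inhibition(tab)
  }
  names(primary) <- as.character(conds)
  structure(list(model_id = model_id, kind = dataset$kind,
                 primary_fits = primary, param_table = tab,
                 secondary_fit = secondary),
            class = "pm_two_step")
}

#' @export
print.pm_two_step <- function(x, ...) {
  cat(sprintf("<pm_two_step> %s (%s), %d conditions\n",
              x$model_id, x$kind, length(x$primary_fits)))
  print(x$param_table)
  cat("secondary stage:\n")
  print(x$secondary_fit)
  invisible(x)
}
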