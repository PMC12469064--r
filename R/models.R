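# Primary models: sigmoid growth curves and inactivation (survival) curves.
#
# User-facing populations are always log10 CFU (per g or cm2).  The Baranyi
# and Huang models are defined on the natural-log scale; their evaluators
# convert at the interface so every function in the package speaks log10.

#' Validate growth-model parameters
#'
#' @param x0,xmax initial and maximum population (log10 CFU/g).
#' @param rate maximum growth rate (log10/h for Gompertz/Logistic `rmax`,
#'   1/h for Baranyi/Huang `mumax`).
#' @param lag lag-phase duration (h).
#' @noRd
check_growth_params <- function(x0, xmax, rate, lag) {
  check_num(x0, "x0", 1); check_num(xmax, "xmax", 1)
  check_num(rate, "rate", 1); check_num(lag, "lag", 1)
  if (xmax <= x0) stop_pm("xmax must exceed x0", "pm_param_error")
  if (rate <= 0) stop_pm("growth rate must be positive", "pm_param_error")
  if (lag < 0) stop_pm("lag must be non-negative", "pm_param_error")
  invisible(TRUE)
}

#' Modified Gompertz growth model
#'
#' Sigmoid growth of the log10 count between `x0` and the asymptote `xmax`,
#' with maximum slope `rmax` reached after a lag of `lag` hours:
#' \deqn{x(t) = x_0 + (x_{max}-x_0)\exp\{-\exp[r_{max} e (\lambda-t)/(x_{max}-x_0) + 1]\}}
#'
#' @param t time (h), vectorised.
#' @param x0 initial population (log10 CFU/g).
#' @param xmax maximum population (log10 CFU/g); must exceed `x0`.
#' @param rmax maximum growth rate on the log10 scale (log10 CFU/g per h).
#' @param lag lag-phase duration \eqn{\lambda} (h).
#' @return Population at `t` (log10 CFU/g).
#' @examples
#' growth_gompertz(c(0, 10, 50), x0 = 3, xmax = 9, rmax = 0.2, lag = 5)
#' @family primary growth models
#' @export
growth_gompertz <- function(t, x0, xmax, rmax, lag) {
  check_growth_params(x0, xmax, rmax, lag)
  check_num(t, "t")
  span <- xmax - x0
  z <- rmax * exp(1) / span * (lag - t) + 1
  x0 + span * exp(-exp(z))
}

#' Logistic growth model
#'
#' Symmetric sigmoid on the log10 scale:
#' \deqn{x(t) = x_0 + (x_{max}-x_0) / (1 + \exp[4 r_{max}(\lambda-t)/(x_{max}-x_0) + 2])}
#'
#' @inheritParams growth_gompertz
#' @return Population at `t` (log10 CFU/g).
#' @family primary growth models
#' @export
growth_logistic <- function(t, x0, xmax, rmax, lag) {
  check_growth_params(x0, xmax, rmax, lag)
  check_num(t, "t")
  span <- xmax - x0
  z <- 4 * rmax / span * (lag - t) + 2
  x0 + span / (1 + exp(z))
}

# Baranyi-Roberts adjustment function F(t), natural-log scale.
# Equivalent to the h0 = mumax*lag parameterisation (q0 = 1/(exp(mumax*lag)-1)).
baranyi_ft <- function(t, mumax, lag) {
  # exp(-mu*t) + exp(-mu*lag) - exp(-mu*(t+lag)); all terms in (0, 1]
  t + log(exp(-mumax * t) + exp(-mumax * lag) - exp(-mumax * (t + lag))) / mumax
}

#' Baranyi-Roberts growth model
#'
#' Explicit solution of the Baranyi-Roberts system under constant
#' conditions, using the adjustment function
#' \eqn{F(t) = t + \ln(e^{-\mu t} + e^{-\mu\lambda} - e^{-\mu(t+\lambda)})/\mu}.
#' The model is formulated on the natural-log scale; this evaluator takes
#' and returns log10 populations, converting internally (ln = log10 x ln 10).
#' Evaluation is overflow-safe for arbitrarily large `mumax * t`.
#'
#' @param t time (h), vectorised.
#' @param x0 initial population (log10 CFU/g).
#' @param xmax maximum population (log10 CFU/g).
#' @param mumax maximum specific growth rate (1/h, natural-log scale).
#' @param lag lag-phase duration (h).
#' @return Population at `t` (log10 CFU/g).
#' @family primary growth models
#' @export
growth_baranyi <- function(t, x0, xmax, mumax, lag) {
  check_growth_params(x0, xmax, mumax, lag)
  check_num(t, "t")
  y0 <- x0 * LN10
  d <- (xmax - x0) * LN10
  a <- mumax * baranyi_ft(t, mumax, lag)
  # y = y0 + A - log(1 - exp(-d) + exp(A - d)), stabilised
  y <- y0 + a - log_sum_exp2(log1p(-exp(-d)), a - d)
  y / LN10
}

# Huang transition function B(t) with the published transition coefficient 4.
huang_bt <- function(t, lag) {
  t + 0.25 * (log1pexp(-4 * (t - lag)) - log1pexp(4 * lag))
}

#' Huang growth model
#'
#' Huang's full-range growth model with transition function
#' \eqn{B(t) = t + \frac{1}{4}\ln\frac{1+e^{-4(t-\lambda)}}{1+e^{4\lambda}}}.
#' Natural-log formulation evaluated through a log10 interface, like
#' [growth_baranyi()].
#'
#' @inheritParams growth_baranyi
#' @return Population at `t` (log10 CFU/g).
#' @family primary growth models
#' @export
growth_huang <- function(t, x0, xmax, mumax, lag) {
  check_growth_params(x0, xmax, mumax, lag)
  check_num(t, "t")
  y0 <- x0 * LN10
  ymax <- xmax * LN10
  e <- exp(y0 - ymax)
  b <- huang_bt(t, lag)
  y <- y0 - log(e + (1 - e) * exp(-mumax * b))
  y / LN10
}

#' @noRd
check_inact_params <- function(logN0, k = NULL, logNres = NULL,
                               delta = NULL, p = NULL) {
  check_num(logN0, "logN0", 1)
  if (!is.null(k)) {
    check_num(k, "k", 1)
    if (k < 0) stop_pm("inactivation rate k must be non-negative", "pm_param_error")
  }
  if (!is.null(logNres)) {
    check_num(logNres, "logNres", 1)
    if (logNres >= logN0) {
      stop_pm("residual tail logNres must lie below logN0", "pm_param_error")
    }
  }
  if (!is.null(delta)) {
    check_num(delta, "delta", 1)
    if (delta <= 0) stop_pm("delta must be positive", "pm_param_error")
  }
  if (!is.null(p)) {
    check_num(p, "p", 1)
    if (p <= 0) stop_pm("shape p must be positive", "pm_param_error")
  }
  invisible(TRUE)
}

#' Log-Linear inactivation model
#'
#' First-order decline of the log10 count, \eqn{\log N(t) = \log N_0 - k t}.
#'
#' @param t exposure time (s), vectorised.
#' @param logN0 initial population (log10).
#' @param k inactivation rate constant (1/s).
#' @return Population at `t` (log10).
#' @family inactivation models
#' @export
inact_loglinear <- function(t, logN0, k) {
  check_inact_params(logN0, k = k)
  check_num(t, "t")
  logN0 - k * t
}

#' Log-Linear with Tail inactivation model
#'
#' Exponential decay of the log10 count toward a resistant tail:
#' \eqn{\log N(t) = (\log N_0 - \log N_{res}) e^{-k t} + \log N_{res}}.
#'
#' @inheritParams inact_loglinear
#' @param logNres residual tail population (log10), below `logN0`.
#' @return Population at `t` (log10).
#' @family inactivation models
#' @export
inact_loglinear_tail <- function(t, logN0, k, logNres) {
  check_inact_params(logN0, k = k, logNres = logNres)
  check_num(t, "t")
  (logN0 - logNres) * exp(-k * t) + logNres
}

#' Weibull inactivation model
#'
#' \eqn{\log N(t) = \log N_0 - (t/\delta)^p} where \eqn{\delta} is the time
#' to the first decimal reduction and `p` the shape factor (p < 1 tailing,
#' p > 1 shouldering).  At `t = delta` the curve has dropped exactly one
#' log10 unit for every `p`.
#'
#' @inheritParams inact_loglinear
#' @param delta time to first log10 reduction (s), positive.
#' @param p shape factor (dimensionless), positive.
#' @return Population at `t` (log10).
#' @family inactivation models
#' @export
inact_weibull <- function(t, logN0, delta, p) {
  check_inact_params(logN0, delta = delta, p = p)
  check_num(t, "t")
  logN0 - (t / delta)^p
}

#' Convert between log10-scale and specific growth rates
#'
#' The modified Gompertz and Logistic models estimate `rmax` on the log10
#' scale while Baranyi and Huang use the specific rate `mumax` on the
#' natural-log scale; the two differ by a factor of ln(10).
#'
#' @param rmax maximum growth rate, log10 CFU per h.
#' @param mumax maximum specific growth rate, 1/h.
#' @return `rmax_to_mumax()` returns `rmax * log(10)`;
#'   `mumax_to_rmax()` returns `mumax / log(10)`.
#' @examples
#' rmax_to_mumax(0.1)        # 0.2302585
#' mumax_to_rmax(rmax_to_mumax(0.1))
#' @export
rmax_to_mumax <- function(rmax) {
  check_num(rmax, "rmax")
  rmax * LN10
}

#' @rdname rmax_to_mumax
#' @export
mumax_to_rmax <- function(mumax) {
  check_num(mumax, "mumax")
  mumax / LN10
}

# Internal dispatcher used by fitting and simulation.  `params` is a named
# numeric vector in the user-facing (log10) parameterisation of each model.
GROWTH_MODELS <- c("gompertz", "logistic", "baranyi", "huang")
INACT_MODELS <- c("loglinear", "loglinear_tail", "weibull")

#' @noRd
growth_param_names <- function(model_id) {
  switch(model_id,
    gompertz = ,
    logistic = c("x0", "xmax", "rmax", "lag"),
    baranyi = ,
    huang = c("x0", "xmax", "mumax", "lag"),
    stop_pm(sprintf("unknown growth model '%s'", model_id), "pm_model_error")
  )
}

#' @noRd
inact_param_names <- function(model_id) {
  switch(model_id,
    loglinear = c("logN0", "k"),
    loglinear_tail = c("logN0", "k", "logNres"),
    weibull = c("logN0", "delta", "p"),
    stop_pm(sprintf("unknown inactivation model '%s'", model_id), "pm_model_error")
  )
}

# Clamped evaluation used inside optimisation loops: box bounds on the
# individual parameters cannot express joint constraints (e.g. xmax > x0),
# so evaluate a softly clamped parameter vector instead of erroring when an
# intermediate Levenberg-Marquardt step wanders into an invalid corner.
#' @noRd
eval_primary_safe <- function(model_id, t, params) {
  p <- params
  if (model_id %in% GROWTH_MODELS) {
    p[["xmax"]] <- max(p[["xmax"]], p[["x0"]] + 0.05)
    rn <- if (model_id %in% c("baranyi", "huang")) "mumax" else "rmax"
    p[[rn]] <- max(p[[rn]], 1e-8)
    p[["lag"]] <- max(p[["lag"]], 0)
  } else {
    if (!is.na(p["k"])) p[["k"]] <- max(p[["k"]], 0)
    if (!is.na(p["delta"])) p[["delta"]] <- max(p[["delta"]], 1e-6)
    if (!is.na(p["p"])) p[["p"]] <- max(p[["p"]], 0.01)
    if (!is.na(p["logNres"])) {
      p[["logNres"]] <- min(p[["logNres"]], p[["logN0"]] - 0.05)
    }
  }
  eval_primary(model_id, t, p)
}

#' Evaluate a primary model by identifier
#'
#' Generic entry point used throughout the fitting, simulation and CLI
#' layers.  `params` is a named numeric vector matching the model's
#' user-facing parameterisation (see the individual evaluators).
#'
#' @param model_id one of `"gompertz"`, `"logistic"`, `"baranyi"`,
#'   `"huang"`, `"loglinear"`, `"loglinear_tail"`, `"weibull"`.
#' @param t time vector (h for growth, s for inactivation).
#' @param params named numeric vector of model parameters.
#' @return Predicted log10 population at `t`.
#' @export
eval_primary <- function(model_id, t, params) {
  p <- as.list(params)
  switch(model_id,
    gompertz = growth_gompertz(t, p$x0, p$xmax, p$rmax, p$lag),
    logistic = growth_logistic(t, p$x0, p$xmax, p$rmax, p$lag),
    baranyi = growth_baranyi(t, p$x0, p$xmax, p$mumax, p$lag),
    huang = growth_huang(t, p$x0, p$xmax, p$mumax, p$lag),
    loglinear = inact_loglinear(t, p$logN0, p$k),
    loglinear_tail = inact_loglinear_tail(t, p$logN0, p$k, p$logNres),
    weibull = inact_weibull(t, p$logN0, p$delta, p$p),
    stop_pm(sprintf("unknown model '%s'", model_id), "pm_model_error")
  )
}
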