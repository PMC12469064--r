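# Seeded generator of growth and inactivation datasets with known
# parameters, emulating isothermal chicken-storage growth experiments
# (2-20 degC) and chlorine surface-inactivation experiments
# (50-200 mg/L, 0-360 s).

# default exposure grid for inactivation experiments (s)
INACT_TIMES <- c(0, 15, 30, 60, 120, 180, 240, 300, 360)

#' Describe a simulation experiment
#'
#' Collects everything a reproducible simulated experiment needs: the
#' primary model, its true parameters (either one kinetic set shared by
#' all conditions or a secondary parameter set from which per-condition
#' kinetics are derived), the conditions, time grids, the Gaussian noise
#' level on the log10 scale, replicate count and seed.
#'
#' @param kind `"growth"` or `"inhibition"`.
#' @param model_id primary model identifier.
#' @param primary named list/vector of primary parameters.  Growth:
#'   `x0`, `xmax`, plus `rmax`/`mumax` and `lag` when no secondary set is
#'   given.  Inactivation: `logN0`, plus `delta`/`k` (`p`, `logNres` as
#'   the model requires) when no secondary set is given.
#' @param secondary optional named list: growth `b1`, `xmin`, `b2`;
#'   inactivation `a`, `b` (the per-condition `delta` or `k` then comes
#'   from [inhib_secondary()]).
#' @param conditions environmental values, one curve per condition (times
#'   `replicates`).
#' @param times optional time grid (vector applied to every condition, or
#'   list of vectors per condition).  Defaults: growth - 15 points from 0
#'   to the time the true curve covers 99% of its span; inactivation -
#'   0-360 s at the standard 9 exposure times.
#' @param noise_sd Gaussian noise sd in log10 units (default 0.15 growth,
#'   0.10 inactivation).
#' @param replicates replicate curves per condition.
#' @param seed RNG seed.
#' @return A `pm_sim_spec` object for [simulate_growth()] /
#'   [simulate_inhibition()].
#' @export
simulation_spec <- function(kind = c("growth", "inhibition"), model_id,
                            primary, secondary = NULL, conditions,
                            times = NULL, noise_sd = NULL, replicates = 1,
                            seed = DEFAULT_SEED) {
  kind <- match.arg(kind)
  if (is.null(noise_sd)) noise_sd <- if (kind == "growth") 0.15 else 0.10
  if (noise_sd < 0) stop_pm("noise_sd must be non-negative", "pm_domain_error")
  check_num(conditions, "conditions")
  structure(list(kind = kind, model_id = model_id,
                 primary = as.list(primary), secondary = secondary,
                 conditions = conditions, times = times,
                 noise_sd = noise_sd, replicates = replicates, seed = seed),
            class = "pm_sim_spec")
}

# time at which the true curve reaches x0 + frac * (xmax - x0)
#' @noRd
time_to_fraction <- function(model_id, params, frac = 0.99) {
  target <- params[["x0"]] + frac * (params[["xmax"]] - params[["x0"]])
  f <- function(t) eval_primary(model_id, t, unlist(params)) - target
  upper <- 10
  while (f(upper) < 0 && upper < 1e8) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-8)$root
}

#' @noRd
true_growth_params <- function(spec, X) {
  p <- spec$primary
  ln_scale <- spec$model_id %in% c("baranyi", "huang")
  if (!is.null(spec$secondary)) {
    s <- spec$secondary
    mu <- ratkowsky_mu(X, s$b1, s$xmin)
    if (mu <= 0) {
      stop_pm(sprintf("condition %g is at or below xmin: no growth", X),
              "pm_domain_error")
    }
    lag <- lag_from_mu(mu, s$b2)
    if (ln_scale) {
      c(x0 = p$x0, xmax = p$xmax, mumax = mu, lag = lag)
    } else {
      c(x0 = p$x0, xmax = p$xmax, rmax = mumax_to_rmax(mu), lag = lag)
    }
  } else {
    unlist(p)[growth_param_names(spec$model_id)]
  }
}

#' @noRd
true_inact_params <- function(spec, X) {
  p <- spec$primary
  if (!is.null(spec$secondary)) {
    s <- spec$secondary
    kin <- inhib_secondary(X, s$a, s$b, check_positive = TRUE)
    switch(spec$model_id,
      loglinear = c(logN0 = p$logN0, k = kin),
      loglinear_tail = c(logN0 = p$logN0, k = kin, logNres = p$logNres),
      weibull = c(logN0 = p$logN0, delta = kin, p = p$p)
    )
  } else {
    unlist(p)[inact_param_names(spec$model_id)]
  }
}

#' @noRd
spec_times <- function(spec, idx, default) {
  if (is.null(spec$times)) return(default)
  if (is.list(spec$times)) spec$times[[idx]] else spec$times
}

#' Simulate a growth dataset from known parameters
#'
#' For every condition the true curve is evaluated from the primary
#' parameters (derived through the secondary model when one is supplied)
#' and Gaussian noise is added on the log10 scale.  Identical seeds give
#' identical datasets.  The generating parameters are attached as
#' attribute `"truth"`.
#'
#' @param spec a [simulation_spec()] of kind `"growth"`.
#' @return A [pm_dataset()] of kind `"growth"`.
#' @export
simulate_growth <- function(spec) {
  stopifnot(inherits(spec, "pm_sim_spec"), spec$kind == "growth")
  curves <- with_seed(spec$seed, {
    out <- list()
    for (r in seq_len(spec$replicates)) {
      for (i in seq_along(spec$conditions)) {
        X <- spec$conditions[i]
        pars <- true_growth_params(spec, X)
        tt <- spec_times(spec, i,
                         seq(0, time_to_fraction(spec$model_id, as.list(pars)),
                             length.out = 15))
        vals <- eval_primary(spec$model_id, tt, pars) +
          stats::rnorm(length(tt), 0, spec$noise_sd)
        out[[length(out) + 1]] <- pm_curve(tt, vals, X)
      }
    }
    out
  })
  ds <- pm_dataset(curves, kind = "growth")
  attr(ds, "truth") <- list(model_id = spec$model_id,
                            primary = spec$primary,
                            secondary = spec$secondary)
  ds
}

#' Simulate an inactivation dataset from known parameters
#'
#' As [simulate_growth()] for survival curves: per condition the kinetic
#' parameter (delta or k) comes from the logarithmic secondary model when
#' secondary coefficients are supplied, with `logN0` (and shape `p` or
#' tail `logNres`) shared across conditions.
#'
#' @param spec a [simulation_spec()] of kind `"inhibition"`.
#' @return A [pm_dataset()] of kind `"inhibition"`.
#' @export
simulate_inhibition <- function(spec) {
  stopifnot(inherits(spec, "pm_sim_spec"), spec$kind == "inhibition")
  curves <- with_seed(spec$seed, {
    out <- list()
    for (r in seq_len(spec$replicates)) {
      for (i in seq_along(spec$conditions)) {
        X <- spec$conditions[i]
        pars <- true_inact_params(spec, X)
        tt <- spec_times(spec, i, INACT_TIMES)
        vals <- eval_primary(spec$model_id, tt, pars) +
          stats::rnorm(length(tt), 0, spec$noise_sd)
        out[[length(out) + 1]] <- pm_curve(
          tt, vals, X, condition_name = "chlorine",
          response_units = "log10 CFU/cm2")
      }
    }
    out
  })
  ds <- pm_dataset(curves, kind = "inhibition")
  attr(ds, "truth") <- list(model_id = spec$model_id,
                            primary = spec$primary,
                            secondary = spec$secondary)
  ds
}
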