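# Estimation: zero-noise identifiability, nesting, secondary round trips,
# two-step composition and one-step optimality.

test_that("all four growth models are exactly identifiable at zero noise", {
  tt <- seq(0, 72, length.out = 20)
  for (m in c("gompertz", "logistic", "baranyi", "huang")) {
    rate_name <- if (m %in% c("baranyi", "huang")) "mumax" else "rmax"
    truth <- stats::setNames(c(3, 9, if (rate_name == "mumax") 0.2 else 0.1, 5),
                             c("x0", "xmax", rate_name, "lag"))
    curve <- pm_curve(tt, eval_primary(m, tt, truth), 20)
    fit <- fit_primary_growth(curve, m)
    expect_equal(fit$estimates, truth, tolerance = 1e-6, info = m)
    expect_lt(fit$rmse, 1e-6)
  }
})

test_that("all three inactivation models are exactly identifiable at zero noise", {
  tt <- c(0, 15, 30, 60, 120, 180, 240, 300, 360)
  truths <- list(
    loglinear = c(logN0 = 7, k = 0.01),
    loglinear_tail = c(logN0 = 7, k = 0.02, logNres = 3.5),
    weibull = c(logN0 = 7, delta = 20.43, p = 0.33)
  )
  for (m in names(truths)) {
    curve <- pm_curve(tt, eval_primary(m, tt, truths[[m]]), 50)
    fit <- fit_primary_inhibition(curve, m)
    expect_equal(fit$estimates, truths[[m]], tolerance = 1e-6, info = m)
  }
})

test_that("Weibull fitted to log-linear data recovers shape p near 1", {
  tt <- c(0, 15, 30, 60, 120, 180, 240, 300, 360)
  curve <- pm_curve(tt, inact_loglinear(tt, 7, 0.01), 50)
  fit <- fit_primary_inhibition(curve, "weibull")
  expect_equal(fit$estimates[["p"]], 1, tolerance = 1e-4)
  expect_equal(fit$estimates[["delta"]], 100, tolerance = 1e-3)
})

test_that("growth fit beats a brute-force grid-refined oracle on noisy data", {
  set.seed(7)
  tt <- seq(0, 60, length.out = 18)
  truth <- c(x0 = 3, xmax = 9, rmax = 0.15, lag = 8)
  yy <- eval_primary("gompertz", tt, truth) + rnorm(18, 0, 0.2)
  curve <- pm_curve(tt, yy, 15)
  fit <- fit_primary_growth(curve, "gompertz")
  # coarse lattice around plausible values, then local polish
  grid <- expand.grid(x0 = seq(2.5, 3.5, by = 0.25),
                      xmax = seq(8.5, 9.5, by = 0.25),
                      rmax = seq(0.05, 0.3, by = 0.05),
                      lag = seq(0, 16, by = 2))
  sse_at <- function(p) {
    # Nelder-Mead may step outside the valid parameter region
    if (p[2] <= p[1] + 0.05 || p[3] <= 0 || p[4] < 0) return(1e10)
    sum((yy - eval_primary("gompertz", tt,
      c(x0 = p[1], xmax = p[2], rmax = p[3], lag = p[4])))^2)
  }
  sses <- apply(as.matrix(grid), 1, sse_at)
  best <- as.numeric(grid[which.min(sses), ])
  polish <- stats::optim(best, sse_at, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
  expect_lte(fit$sse, polish$value + 1e-8)
})

test_that("degenerate curves are rejected with diagnostics", {
  tt <- seq(0, 50, length.out = 10)
  expect_error(fit_primary_growth(pm_curve(tt, 8 - 0.05 * tt, 4), "baranyi"),
               "decline")
  expect_error(fit_primary_growth(pm_curve(tt, rep(5, 10) +
                                             c(0.01 * seq_len(10)), 4),
                                  "baranyi"), "one log10")
  expect_error(fit_primary_inhibition(pm_curve(tt, 3 + 0.05 * tt, 50),
                                      "weibull"), "increase")
  expect_error(fit_primary_growth(pm_curve(tt[1:4], c(3, 4, 5, 6), 4),
                                  "baranyi"), "at least 5")
})

test_that("secondary growth fitting recovers exact and self-consistent inputs", {
  X <- c(2, 4, 10, 15, 20)
  mu <- ratkowsky_mu(X, 0.0014, -9.24)
  tab <- data.frame(condition = X, mumax = mu, lag = 1.29 / mu)
  fit <- fit_secondary_growth(tab)
  expect_equal(fit$estimates[["b1"]], 0.0014, tolerance = 1e-6)
  expect_equal(fit$estimates[["xmin"]], -9.24, tolerance = 1e-6)
  expect_equal(fit$estimates[["b2"]], 1.29, tolerance = 1e-6)
})

test_that("secondary growth estimates stay within Monte-Carlo uncertainty", {
  set.seed(11)
  X <- c(2, 4, 10, 15, 20)
  mu_true <- ratkowsky_mu(X, 0.0014, -9.24)
  ests <- replicate(60, {
    tab <- data.frame(condition = X,
                      mumax = pmax(mu_true * (1 + rnorm(5, 0, 0.05)), 1e-4))
    coef(fit_secondary_growth(tab))[c("b1", "xmin")]
  })
  expect_equal(mean(ests["b1", ]), 0.0014, tolerance = 0.15)
  expect_equal(mean(ests["xmin", ]), -9.24, tolerance = 0.15)
})

test_that("secondary inactivation fitting is the log10 regression", {
  X <- c(50, 100, 150, 200)
  tab <- data.frame(condition = X, value = inhib_secondary(X, 64.49, 26.92))
  fit <- fit_secondary_inhibition(tab)
  expect_equal(fit$estimates[["a"]], 64.49, tolerance = 1e-9)
  expect_equal(fit$estimates[["b"]], 26.92, tolerance = 1e-9)
  # noisy round trip stays near the truth
  set.seed(3)
  tab$value <- tab$value + rnorm(4, 0, 0.5)
  fit2 <- fit_secondary_inhibition(tab)
  expect_equal(fit2$estimates[["a"]], 64.49, tolerance = 0.1)
})

test_that("two-step run composes the primary and secondary stages exactly", {
  spec <- simulation_spec("growth", "baranyi",
                          primary = list(x0 = 3.5, xmax = 9.5),
                          secondary = list(b1 = 0.0014, xmin = -9.24,
                                           b2 = 1.29),
                          conditions = c(4, 10, 15, 20),
                          noise_sd = 0.1, seed = 21)
  ds <- simulate_growth(spec)
  ts <- fit_two_step(ds, "baranyi", seed = 5)
  manual_primary <- lapply(ds$curves, fit_primary_growth,
                           model_id = "baranyi", seed = 5)
  for (i in seq_along(manual_primary)) {
    expect_equal(ts$primary_fits[[i]]$estimates,
                 manual_primary[[i]]$estimates)
  }
  manual_tab <- data.frame(
    condition = sapply(ds$curves, `[[`, "condition"),
    mumax = sapply(manual_primary, function(f) f$estimates[["mumax"]]),
    lag = sapply(manual_primary, function(f) f$estimates[["lag"]]))
  manual_secondary <- fit_secondary_growth(manual_tab, seed = 5)
  expect_equal(ts$secondary_fit$estimates, manual_secondary$estimates)
})

test_that("two-step inactivation recovers the generating secondary response", {
  spec <- simulation_spec("inhibition", "weibull",
                          primary = list(logN0 = 7, p = 0.33),
                          secondary = list(a = 64.49, b = 26.92),
                          conditions = c(50, 100, 150, 200),
                          noise_sd = 0.05, seed = 33)
  ts <- fit_two_step(simulate_inhibition(spec), "weibull")
  expect_equal(ts$secondary_fit$estimates[["a"]], 64.49, tolerance = 0.15)
  expect_equal(ts$secondary_fit$estimates[["b"]], 26.92, tolerance = 0.15)
})

test_that("one-step growth is exactly identifiable at zero noise", {
  for (m in c("gompertz", "baranyi")) {
    spec <- simulation_spec("growth", m,
                            primary = list(x0 = 3.97, xmax = 9.66),
                            secondary = list(b1 = 0.0014, xmin = -9.24,
                                             b2 = 1.29),
                            conditions = c(2, 4, 10, 15, 20),
                            noise_sd = 0, seed = 1)
    fit <- fit_one_step_growth(simulate_growth(spec), m)
    truth <- c(x0 = 3.97, xmax = 9.66, xmin = -9.24, b1 = 0.0014, b2 = 1.29)
    expect_lt(max(abs(fit$estimates - truth) / abs(truth)), 1e-6)
  }
})

test_that("one-step inactivation is exactly identifiable at zero noise", {
  spec <- simulation_spec("inhibition", "weibull",
                          primary = list(logN0 = 7, p = 0.33),
                          secondary = list(a = 64.49, b = 26.92),
                          conditions = c(50, 100, 150, 200),
                          noise_sd = 0, seed = 1)
  fit <- fit_one_step_inhibition(simulate_inhibition(spec), "weibull")
  truth <- c(logN0 = 7, a = 64.49, b = 26.92, p = 0.33)
  expect_lt(max(abs(fit$estimates - truth) / abs(truth)), 1e-6)
})

test_that("one-step joint SSE never exceeds the frozen two-step reconstruction", {
  spec <- simulation_spec("growth", "gompertz",
                          primary = list(x0 = 3.97, xmax = 9.66),
                          secondary = list(b1 = 0.0014, xmin = -9.24,
                                           b2 = 1.29),
                          conditions = c(2, 4, 10, 15, 20),
                          noise_sd = 0.3, seed = 17)
  ds <- simulate_growth(spec)
  one <- fit_one_step_growth(ds, "gompertz")
  two <- fit_two_step(ds, "gompertz")
  frozen <- c(
    x0 = mean(sapply(two$primary_fits, function(f) f$estimates[["x0"]])),
    xmax = mean(sapply(two$primary_fits, function(f) f$estimates[["xmax"]])),
    xmin = two$secondary_fit$estimates[["xmin"]],
    b1 = two$secondary_fit$estimates[["b1"]],
    b2 = two$secondary_fit$estimates[["b2"]])
  expect_lte(one$sse, one_step_growth_sse(ds, "gompertz", frozen) + 1e-8)
})

test_that("estimator bias shrinks as curves get denser", {
  # consistency check at n in {10, 40, 160} points per curve
  biases <- sapply(c(10, 40, 160), function(n) {
    errs <- sapply(1:12, function(r) {
      set.seed(1000 * n + r)
      tt <- seq(0, 72, length.out = n)
      yy <- growth_baranyi(tt, 3, 9, 0.25, 5) + rnorm(n, 0, 0.2)
      fit <- fit_primary_growth(pm_curve(tt, yy, 20), "baranyi",
                                n_starts = 4)
      fit$estimates[["mumax"]] - 0.25
    })
    abs(mean(errs))
  })
  expect_lt(biases[3], biases[1] + 0.01)
  # 12 replicates resolve the mean to roughly +/- 0.01; the bound reflects that
  expect_lt(biases[3], 0.02)
})

test_that("reported RMSE and R2 are recomputable from stored residuals", {
  set.seed(5)
  tt <- seq(0, 60, length.out = 15)
  yy <- growth_baranyi(tt, 3, 9, 0.25, 5) + rnorm(15, 0, 0.2)
  fit <- fit_primary_growth(pm_curve(tt, yy, 20), "baranyi")
  obs <- fit$fitted + fit$residuals
  expect_identical(fit$rmse, rmse(obs, fit$fitted, s = fit$n_params))
  expect_identical(fit$r2, r_squared(obs, fit$fitted))
})
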