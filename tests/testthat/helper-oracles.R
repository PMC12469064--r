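# Independent oracles used across the suite.

# Exhaustive two-sided signed-rank p-value: enumerate all 2^n sign
# assignments of the ranked absolute differences.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  stats_all <- vapply(seq_len(2^n) - 1, function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[signs])
  }, 0)
  p <- mean(abs(stats_all - mu) >= abs(v_obs - mu) - 1e-9)
  p
}

# Baranyi-Roberts ODE system in natural log, q0 = 1/(exp(mu*lag)-1)
baranyi_ode_log10 <- function(t, x0, xmax, mumax, lag) {
  y0 <- x0 * log(10); ymax <- xmax * log(10)
  q0 <- 1 / (exp(mumax * lag) - 1)
  deriv <- function(t, state, parms) {
    y <- state[1]; q <- state[2]
    list(c(mumax * q / (1 + q) * (1 - exp(y - ymax)), mumax * q))
  }
  out <- deSolve::ode(c(y = y0, q = q0), times = t, func = deriv,
                      parms = NULL, rtol = 1e-10, atol = 1e-10)
  out[, "y"] / log(10)
}

random_growth_params <- function() {
  x0 <- runif(1, 2, 5)
  c(x0 = x0, xmax = x0 + runif(1, 2, 6), rate = runif(1, 0.05, 0.8),
    lag = runif(1, 0, 20))
}

random_inact_params <- function() {
  logN0 <- runif(1, 5, 8)
  list(loglinear = c(logN0 = logN0, k = runif(1, 0.002, 0.05)),
       loglinear_tail = c(logN0 = logN0, k = runif(1, 0.005, 0.05),
                          logNres = logN0 - runif(1, 2, 4)),
       weibull = c(logN0 = logN0, delta = runif(1, 5, 80),
                   p = runif(1, 0.2, 2)))
}

# quick synthetic growth dataset shared by ML tests
ml_growth_df <- function(seed, noise_sd = 0.3) {
  spec <- simulation_spec("growth", "baranyi",
                          primary = list(x0 = 3.5, xmax = 9.5),
                          secondary = list(b1 = 0.0014, xmin = -9.24,
                                           b2 = 1.29),
                          conditions = c(2, 4, 10, 15, 20),
                          noise_sd = noise_sd, seed = seed)
  as.data.frame(simulate_growth(spec))
}
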