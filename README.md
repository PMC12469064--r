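# predmicro

Predictive-microbiology modelling in R: classical growth and
inactivation kinetics and machine-learning regression on one common
interface, with uncertainty quantification throughout.

The package is for food microbiologists and risk assessors who fit
log-count time series. It provides:

* **Primary growth models** — modified Gompertz, Logistic,
  Baranyi–Roberts and Huang — describing the sigmoid rise of a log10
  count x(t) from an initial level x₀ through a lag phase λ (h) to a
  maximum x_max, at maximum specific rate µ_max (1/h; log10-scale rates
  r_max are converted by µ_max = r_max·ln 10).
* **Primary inactivation models** — Log-Linear
  (log N(t) = log N₀ − kt), Log-Linear + Tail
  (log N(t) = (log N₀ − log N_res)e^(−kt) + log N_res) and Weibull
  (log N(t) = log N₀ − (t/δ)^p), where δ is the time (s) to the first
  decimal reduction and p the shape factor.
* **Secondary models** linking kinetics to one environmental variable:
  µ_max(X) = b₁(X − X_min)², λ = b₂/µ_max for growth versus
  temperature, and k or δ = a − b·log₁₀(X) for inactivation versus
  disinfectant concentration.
* **Two estimation strategies**: the classical two-step workflow (fit
  each curve, regress the kinetic estimates on the environment) and
  one-step global fitting, in which the secondary model is substituted
  into the primary equation and all parameters are estimated
  simultaneously by multi-start Levenberg–Marquardt least squares.
* **Uncertainty**: Gauss–Newton parameter covariance s²(JᵀJ)⁻¹,
  standard errors, delta-method 95 % prediction bands
  (ŷ ± 1.96·σ_ŷ with σ²_ŷ = ∇fᵀC∇f + s²), and percentile-bootstrap
  bands (B = 100) where no analytic variance exists.
* **A machine-learning workflow** (Gaussian process, support vector and
  random forest regression on time + one condition) with z-score
  scaling, small-sample augmentation, stratified 80/20 splitting,
  5-fold cross-validation and 95 % bands — so data-driven and
  mechanistic predictions can be compared on the same datasets, e.g.
  with the paired Wilcoxon signed-rank test.
* **A seeded synthetic-data generator** emulating isothermal growth
  experiments (2–20 °C) and chlorine surface-inactivation experiments
  (50–200 mg/L, 0–360 s), used by the validation suite.

## Worked example

Simulate a four-temperature growth study from known kinetics, then
estimate those kinetics both ways:

```r
library(predmicro)

spec <- simulation_spec(
  kind = "growth", model_id = "baranyi",
  primary = list(x0 = 3.5, xmax = 9.5),
  secondary = list(b1 = 0.0014, xmin = -9.24, b2 = 1.29),
  conditions = c(4, 10, 15, 20), noise_sd = 0.15, seed = 20250910)
ds <- simulate_growth(spec)

two <- fit_two_step(ds, "baranyi")
two
#> <pm_two_step> baranyi (growth), 4 conditions
#>   condition     mumax      lag
#> 1         4 0.2389944 4.699168
#> 2        10 0.4884327 2.246219
#> 3        15 0.8406894 1.873659
#> 4        20 1.3336794 1.327809
#> secondary stage:
#> <pm_fit> model: ratkowsky  (n = 8, p = 3)
#>      estimate std_error
#> b1    0.00189   0.00018
#> xmin -6.40722   1.09837
#> b2    1.16088   0.08340
#> RMSE = 0.03518, R2 = 0.9963

one <- fit_one_step_growth(ds, "baranyi")
one
#> <pm_fit> model: baranyi_one_step  (n = 60, p = 5)
#>      estimate std_error
#> x0    3.51559   0.07076
#> xmax  9.50853   0.07638
#> xmin -9.10639   0.21100
#> b1    0.00143   0.00004
#> b2    1.37710   0.26808
#> RMSE = 0.1641, R2 = 0.9941
```

The contrast is the point: with only four conditions, the two-step
secondary stage — which sees just four noisy (µ̂_max, λ̂) pairs —
misses the minimum-growth temperature badly (−6.4 °C against a true
−9.24 °C), while the one-step fit, pooling all 60 observations into one
optimisation, lands at −9.11 ± 0.21 °C and recovers b₁ = 0.00143
against a true 0.0014. Delta-method bands for any fitted curve come
from `primary_band(two$primary_fits[["20"]])`, and
`wilcoxon_signed_rank()` compares paired per-dataset RMSEs of two
approaches (five concordant pairs give the exact two-sided floor
p = 0.0625).

The same interface handles inactivation: `simulate_inhibition()`,
`fit_primary_inhibition(curve, "weibull")`,
`fit_one_step_inhibition(ds, "weibull")` (shared shape p and
log N₀, with δ(X) = a − b·log₁₀X), and `fit_ml(features, response,
ml_config("gpr"))` for the data-driven route.

A command-line interface wraps the same functions
(`exec/predmicro`): subcommands `fit-growth`, `fit-inhibition`, `ml`,
`simulate` and `compare`, each writing a JSON or CSV report;
`--seed` makes runs byte-for-byte reproducible.

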