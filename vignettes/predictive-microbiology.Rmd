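---
title: "Modelling microbial growth and inactivation with predmicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling microbial growth and inactivation with predmicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predmicro)
```

## The modelling problem

Food microbiologists describe two processes with kinetic models fitted to
log-count time series. *Growth* under permissive conditions is sigmoidal:
after a lag phase of duration $\lambda$ (h) the log10 count rises from an
initial level $x_0$ at a maximum rate and saturates at a carrying
capacity $x_{max}$. *Inactivation* under a stressor (here, chlorine on a
food-contact surface) is a decline of the log10 count over seconds to
minutes. A **primary model** describes one curve at constant conditions;
a **secondary model** relates the kinetic parameters of the primary
model to an environmental variable such as storage temperature or
disinfectant concentration.

predmicro implements four primary growth models (modified Gompertz,
Logistic, Baranyi–Roberts, Huang), three primary inactivation models
(Log-Linear, Log-Linear + Tail, Weibull), the two secondary relations
used with them, two estimation strategies (two-step and one-step), an
uncertainty layer, and a parallel machine-learning workflow that can be
compared against the mechanistic fits on the same data.

## Primary models and conventions

All user-facing populations are log10 CFU. The modified Gompertz and
Logistic models are natively log10-scale with rate $r_{max}$
(log10 CFU/h); Baranyi and Huang are natural-log models with specific
rate $\mu_{max}$ (1/h). The two rates differ by $\ln 10$:
$\mu_{max} = r_{max}\ln 10$ (`rmax_to_mumax()`). The evaluators for
Baranyi and Huang convert at the interface so that every function in the
package accepts and returns log10 counts, and every growth fit reports a
$\mu_{max}$ on the 1/h scale regardless of the primary model.

Two adjustment functions are not uniquely determined by their common
textual descriptions, so the package fixes them explicitly:

* **Baranyi** uses the explicit Baranyi–Roberts solution with
  $F(t) = t + \frac{1}{\mu_{max}}\ln\!\left(e^{-\mu_{max}t} +
  e^{-\mu_{max}\lambda} - e^{-\mu_{max}(t+\lambda)}\right)$, the
  canonical form equivalent to parameterising the initial physiological
  state as $h_0 = \mu_{max}\lambda$ (or $q_0 = 1/(e^{\mu_{max}\lambda}-1)$).
  The test suite checks this closed form against numerical integration
  of the underlying differential system.
* **Huang** uses the published transition function
  $B(t) = t + \frac{1}{4}\ln\frac{1+e^{-4(t-\lambda)}}{1+e^{4\lambda}}$
  with the standard transition coefficient 4. The coefficient is a
  documented constant of the implementation, not a fitted quantity.

Both evaluators use shifted log-sum-exp arithmetic, so expressions of
the form $e^{\mu_{max} t}$ never overflow even at extreme times
(`growth_baranyi(1e6, ...)` is finite).

The Log-Linear + Tail model is implemented as a decay of the *log*
count toward the tail,
$\log N(t) = (\log N_0 - \log N_{res})e^{-kt} + \log N_{res}$.
A classical alternative (Geeraerd) formulates the decay on arithmetic
counts; the two disagree in the transition region. The form above is
the one this package commits to; users needing the arithmetic-count variant
should treat the fitted parameters as not directly comparable.

The Weibull survival model
$\log N(t) = \log N_0 - (t/\delta)^p$ has the useful invariant that the
curve has dropped exactly one log10 unit at $t = \delta$ for every
shape $p$, and reduces exactly to Log-Linear with $k = 1/\delta$ at
$p = 1$ (both are asserted in the tests).

## Secondary models

The growth-rate response is
$\mu_{max}(X) = b_1 (X - X_{min})^2$, with $X_{min}$ the value of the
environmental variable below which growth ceases. This is the
squared-deviation form of the classical square-root relation (the
square-root relation is usually written
$\sqrt{\mu_{max}} = b(X - X_{min})$ and then squared for use); the
units of $b_1$, 1/(h·°C²) for temperature, are consistent with the
squared form and that is what `ratkowsky_mu()` computes. Below
$X_{min}$ the function returns zero growth rather than a negative rate.
The lag relation is $\lambda = b_2/\mu_{max}$.

For inactivation, $k$ or $\delta$ follows a decreasing logarithmic
response $a - b\log_{10}(X)$. The logarithm base is taken as 10, the
predictive-microbiology convention for concentration responses; with
coefficients on the scale used here, $a - b\log_{10}(50) \approx 19$ s
reproduces the two-step $\delta$ at 50 mg/L, which is the consistency
that fixes the base.

## Two-step and one-step estimation

`fit_two_step()` fits the primary model per condition and regresses the
collected kinetic estimates on the environmental variable. Its weakness
is error propagation: primary-stage estimation error enters the
secondary stage as if it were data. `fit_one_step_growth()` and
`fit_one_step_inhibition()` instead substitute the secondary relation
into the primary model and minimise one joint SSE over every
observation: growth shares $(x_0, x_{max}, X_{min}, b_1, b_2)$ across
all curves ($x_0$ and $x_{max}$ are global: one value
shared across all conditions of a dataset); Weibull inactivation shares
$(\log N_0, a, b, p)$ with $\delta(X) = a - b\log_{10} X$.

All nonlinear fits use Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) inside a seeded multi-start (8 starts by
default): one start from data-driven heuristics — first observation for
$x_0$, maximum for $x_{max}$, steepest 3-point secant for the rate, the
tangent intercept at the steepest point for $\lambda$, the interpolated
time of the first 1-log drop for $\delta$, a line through
$\sqrt{\mu}$ versus $X$ for $(b_1, X_{min})$ — plus jittered variants.
One-step surfaces are multi-modal, so the lowest SSE wins and exact
ties go to the smallest parameter norm. Box bounds keep rates, $b_1$
and $\delta$ positive, $p \in [0.05, 5]$, $\lambda \ge 0$ and
$X_{min}$ below the coldest observed condition; joint constraints that
boxes cannot express (e.g. $x_{max} > x_0$) are enforced by a softly
clamped model evaluation inside the optimiser, and the positivity of
$\delta(X)$ across the fitted range by a smooth penalty residual.
Monotone-decreasing "growth" data, increasing "inactivation" data,
flat curves (span under one log10) and undersized curves are rejected
with diagnostics rather than fitted.

λ is always fitted in two-step primary fits, never fixed, since there
is no defensible universal value; at zero noise every fit operation in
the package recovers its generating parameters to below 1e-6 relative
error (a property the test suite asserts for all seven primary models
and both one-step variants).

## Uncertainty

For least-squares fits the parameter covariance is the Gauss–Newton
approximation $C = s^2 (J^\top J)^{-1}$ with
$s^2 = SSE/(n-p)$ — the quantity Levenberg–Marquardt implementations
expose — rather than the exact Hessian. Pointwise 95% prediction bands
use the delta method,
$\sigma^2_{\hat y}(t) = \nabla f^\top C \nabla f + s^2$ and
$\hat y \pm 1.96\,\sigma_{\hat y}$; the 1.96 normal quantile is fixed
(not a $t$ quantile) to match the formulas this implementation follows.
Gradients default to central finite differences with relative step
1e-6; the machinery reproduces the closed-form simple-linear-regression
standard errors and intervals to 1e-10.

Non-probabilistic regressors get percentile-bootstrap bands
(`bootstrap_band()`): B = 100 refits on row-resampled training data,
bounds at the empirical 2.5th/97.5th percentiles. B is a configuration
default, not a constant: 100 balances cost against tail resolution and
under-resolves extreme tails, which is accepted. Bootstrap runs are
bitwise reproducible under a fixed seed.

## The machine-learning workflow

`fit_ml()` runs the full data-driven pipeline on exactly two features,
time plus one environmental variable (a deliberate scope restriction): canonical row ordering (which makes every
downstream metric invariant to input row order), a stratified 80/20
split on the condition, augmentation of training tables below 750 rows
by resampling with replacement up to exactly 750 with uniform ±0.2
log10 label noise on the resampled responses, z-score scaling
(population SD) fitted on training features only, and one of three
regressors: an in-package Gaussian process (squared-exponential kernel
plus white noise, hyperparameters by marginal-likelihood maximisation
with 5 seeded restarts and analytic gradients), epsilon-SVR with an RBF
kernel (C in {1,10,100}, epsilon in {0.01,0.1}, kernel width at the
median heuristic times {0.5,1,2}, chosen by inner 5-fold CV — a small
fixed grid keeps runs deterministic), or a 500-tree random forest.
Augmentation to exactly the threshold is the minimal faithful choice
where no target count is specified. The split precedes augmentation,
and augmentation is re-derived inside every cross-validation training
fold, so no information flows from held-out rows into training;
decision-tree regression is excluded in favour of its ensemble
(the random forest), which dominates it in practice. GPR bands are analytic
($\hat y \pm 1.96\sigma_{GPR}$, predictive variance including the noise
term); SVR/RFR bands use the bootstrap. RMSE for ML models uses
denominator $n$ (no defined parameter count); mechanistic fits use
$n - s$.

### A caution on augmentation

The augmentation step duplicates feature locations exactly and adds
only small label noise. With the leakage-free split above, a
marginal-likelihood GP then has a strong incentive to shrink its length
scale and memorise per-location means: on a representative synthetic
growth dataset the collapsed solution beats a smooth one by hundreds of
nats, its held-out RMSE is several times worse than SVR's, and the
random forest is similarly location-bound. Favourable held-out metrics under such an augmentation scheme are
only reproducible if augmented copies of test rows leak into
training, which this package refuses to do. The GP's predictive *variance* remains honest — at
unseen inputs it reverts to the prior scale, so its 95% bands keep
near-nominal coverage (asserted in the tests) — but users should treat
augmented-pipeline point predictions at unobserved times with caution,
and prefer datasets large enough (≥ 750 training rows) that the
augmentation never engages.

## Model comparison

`rmse()` (with the $n-s$ denominator), `r_squared()`, and
`wilcoxon_signed_rank()` compare approaches. The signed-rank test drops
zero differences (Wilcoxon's original procedure), shares mid-ranks
among ties, is exact for 25 or fewer untied pairs (equal to brute-force
enumeration over sign assignments, asserted up to n = 12) and otherwise
uses the tie-corrected normal approximation without continuity
correction. The conventional 0.05 threshold is a reporting default,
not a gate. Pairs are per-dataset RMSE values by default; any paired
metric can be supplied.

## The synthetic-data generator

`simulate_growth()` / `simulate_inhibition()` generate datasets with
known truth for validation and parameter-recovery studies. They emulate the structure of benchmark experiments in this field:
isothermal growth at 2–20 °C (by default 15 time points from 0 to the
time the true curve covers 99% of its span, so every phase is sampled)
and chlorine inactivation at 50–200 mg/L over 0–360 s on the standard
9-point exposure grid. Noise is Gaussian on the log10 scale — the field
standard — with defaults 0.15 (growth) and 0.10 (inactivation), typical
residual scatter for plate-count growth and inactivation fits; recovery studies
at other levels state theirs explicitly. The generator does not emulate
detection limits, censoring, or non-Gaussian plate-count error, so
passing recovery tests demonstrate estimator correctness under the
stated noise model, not robustness to those artifacts.

Recovery studies in the tests and the acceptance script use 100
repetitions for single-curve fits, 20 for five-temperature one-step
growth fits and 50 for four-concentration one-step inactivation fits —
sizes at which the Monte-Carlo error of a mean estimate is well below
the reported uncertainties of the quantities being recovered.

## Numerical and degenerate-input choices

* Optimiser tolerances: `ftol = ptol = 1e-15`, up to 500 iterations —
  effectively machine-precision convergence, needed by the zero-noise
  identifiability contract.
* Constant feature columns scale to zeros (guarded divisor) in the
  z-score step.
* A rank-deficient Jacobian at a one-step optimum produces a warning
  and a Moore–Penrose pseudo-inverse covariance instead of an error.
* Every stochastic routine takes an explicit seed (default 20250910)
  and restores the caller's RNG state.
* Reports omit wall-clock timestamps by default so identical seeded
  invocations are byte-identical.

## Limitations

Only constant (static) environmental conditions are supported: no
dynamic temperature profiles, no cardinal or multi-factor secondary
models, no microbial interaction. The ML layer is restricted to two
features by design. Bootstrap intervals are percentile (not BCa), and
the delta-method bands rely on local linearity of the model surface,
which degrades for strongly curved parameterisations at small n.
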