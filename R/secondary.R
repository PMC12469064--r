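# Secondary models: environmental response of the kinetic parameters.

#' Ratkowsky-type growth-rate response
#'
#' Relates the maximum specific growth rate to a single environmental
#' variable X (typically storage temperature):
#' \deqn{\mu_{max}(X) = b_1 (X - X_{min})^2}
#' where `xmin` is the value below which growth ceases.  Note this is the
#' squared-deviation form in which the classical square-root relation is
#' commonly applied after squaring both sides; `b1` then carries units of
#' 1/(h.degC^2) when X is a temperature.  Below `xmin` the function
#' returns 0 (no growth) rather than a negative rate.
#'
#' @param X environmental value(s) (e.g. degC), vectorised.
#' @param b1 regression coefficient (> 0).
#' @param xmin minimum value of X permitting growth.
#' @return Maximum specific growth rate (1/h).
#' @examples
#' ratkowsky_mu(20, b1 = 0.0014, xmin = -9.24)  # about 1.197
#' @family secondary models
#' @export
ratkowsky_mu <- function(X, b1, xmin) {
  check_num(X, "X"); check_num(b1, "b1", 1); check_num(xmin, "xmin", 1)
  if (b1 <= 0) stop_pm("b1 must be positive", "pm_param_error")
  mu <- b1 * (X - xmin)^2
  mu[X <= xmin] <- 0
  mu
}

#' Lag phase from the specific growth rate
#'
#' The lag duration is modelled as inversely proportional to the rate,
#' \eqn{\lambda = b_2 / \mu_{max}}, so that composing with
#' [ratkowsky_mu()] makes the lag shrink as conditions become more
#' permissive.
#'
#' @param mumax maximum specific growth rate (1/h), positive.
#' @param b2 lag-relation coefficient (dimensionless, >= 0).
#' @return Lag-phase duration (h).
#' @family secondary models
#' @export
lag_from_mu <- function(mumax, b2) {
  check_num(mumax, "mumax"); check_num(b2, "b2", 1)
  if (b2 < 0) stop_pm("b2 must be non-negative", "pm_param_error")
  if (any(mumax <= 0)) {
    stop_pm("lag is undefined for a non-positive growth rate", "pm_domain_error")
  }
  b2 / mumax
}

#' Logarithmic inactivation response
#'
#' Secondary model for inactivation kinetics: the rate constant k or the
#' first-decimal-reduction time delta is a decreasing logarithmic function
#' of the environmental variable (e.g. chlorine concentration):
#' \deqn{k \textrm{ or } \delta = a - b \log_{10}(X)}
#'
#' @param X environmental value(s), strictly positive.
#' @param a intercept coefficient (units of k or delta).
#' @param b slope coefficient (units of k or delta per log10 of X).
#' @param check_positive error if any predicted value is non-positive
#'   (useful when X is inside a fitted range where k or delta must stay
#'   physically meaningful).
#' @return Predicted k or delta at `X`.
#' @examples
#' inhib_secondary(50, a = 64.49, b = 26.92)  # about 18.75 s
#' @family secondary models
#' @export
inhib_secondary <- function(X, a, b, check_positive = FALSE) {
  check_num(X, "X"); check_num(a, "a", 1); check_num(b, "b", 1)
  if (any(X <= 0)) stop_pm("X must be strictly positive", "pm_domain_error")
  val <- a - b * log10(X)
  if (check_positive && any(val <= 0)) {
    stop_pm("secondary model predicts a non-positive k/delta inside the range",
            "pm_domain_error")
  }
  val
}
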