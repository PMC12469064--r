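# FitResult container shared by every estimation routine.

#' @noRd
new_fit_result <- function(model_id, estimates, residuals, observed, fitted,
                           jacobian, derived = list(), extra = list()) {
  n <- length(observed)
  p <- length(estimates)
  cv <- param_covariance(jacobian, residuals)
  se <- standard_errors(cv)
  names(se) <- names(estimates)
  sse <- sum(residuals^2)
  sst <- sum((observed - mean(observed))^2)
  structure(c(list(
    model_id = model_id,
    estimates = estimates,
    std_errors = se,
    covariance = cv,
    resid_var = sse / (n - p),
    n_obs = n,
    n_params = p,
    rmse = rmse(observed, fitted, s = p),
    r2 = r_squared(observed, fitted),
    sse = sse,
    sst = sst,
    fitted = fitted,
    residuals = residuals,
    derived = derived
  ), extra), class = "pm_fit")
}

#' @export
print.pm_fit <- function(x, ...) {
  cat(sprintf("<pm_fit> model: %s  (n = %d, p = %d)\n",
              x$model_id, x$n_obs, x$n_params))
  est <- data.frame(estimate = x$estimates, std_error = x$std_errors)
  print(round(est, 5))
  if (length(x$derived)) {
    cat("derived:", paste(sprintf("%s = %.5g", names(x$derived),
                                  unlist(x$derived)), collapse = ", "), "\n")
  }
  cat(sprintf("RMSE = %.4g, R2 = %.4g\n", x$rmse, x$r2))
  invisible(x)
}

#' Extract coefficients from a fit
#' @param object a `pm_fit` object.
#' @param ... unused.
#' @export
coef.pm_fit <- function(object, ...) object$estimates

#' @export
residuals.pm_fit <- function(object, ...) object$residuals

#' @export
fitted.pm_fit <- function(object, ...) object$fitted

#' @export
vcov.pm_fit <- function(object, ...) object$covariance
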