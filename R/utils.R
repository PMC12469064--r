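# Internal numerical helpers shared across modules.

LN10 <- log(10)

#' @noRd
log1pexp <- function(x) {
  # numerically stable log(1 + exp(x))
  out <- numeric(length(x))
  lo <- x <= -37
  hi <- x >= 34
  mid <- !lo & !hi
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out[hi] <- x[hi]
  out
}

#' @noRd
log_sum_exp2 <- function(a, b) {
  # stable log(exp(a) + exp(b)), elementwise with recycling
  m <- pmax(a, b)
  d <- pmin(a, b) - m
  # exp(d) <= 1 always; m == -Inf means both terms are zero
  out <- m + log1p(exp(d))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs the code, and restores the caller's RNG state so
#' seeded internals never perturb user-level random streams.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Central finite-difference Jacobian
#'
#' @param fn function of a numeric parameter vector returning a numeric vector.
#' @param params numeric parameter vector.
#' @param rel_step relative step size.
#' @noRd
numeric_jacobian <- function(fn, params, rel_step = 1e-6) {
  p <- length(params)
  f0 <- fn(params)
  J <- matrix(NA_real_, nrow = length(f0), ncol = p)
  for (i in seq_len(p)) {
    h <- rel_step * max(abs(params[i]), 1e-4)
    up <- params; up[i] <- up[i] + h
    dn <- params; dn[i] <- dn[i] - h
    J[, i] <- (fn(up) - fn(dn)) / (2 * h)
  }
  colnames(J) <- names(params)
  J
}

#' @noRd
stop_pm <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pm_error")))
}

#' @noRd
check_num <- function(x, name, len = NULL) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_pm(sprintf("'%s' must be numeric without missing values", name),
            "pm_domain_error")
  }
  if (!is.null(len) && length(x) != len) {
    stop_pm(sprintf("'%s' must have length %d", name, len), "pm_domain_error")
  }
  invisible(x)
}
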