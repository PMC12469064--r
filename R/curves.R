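# Containers: a single condition's time series (pm_curve) and a collection
# of curves sharing one environmental variable (pm_dataset).

#' Construct a single growth or inactivation curve
#'
#' @param times time points (h for growth, s for inactivation), strictly
#'   increasing.
#' @param values log10 populations, same length as `times`.
#' @param condition value of the environmental variable for this curve
#'   (e.g. 4 for 4 degC).
#' @param condition_name label of the environmental variable
#'   (default "temperature").
#' @param response_units label for the response scale.
#' @return An object of class `pm_curve`.
#' @export
pm_curve <- function(times, values, condition,
                     condition_name = "temperature",
                     response_units = "log10 CFU/g") {
  check_num(times, "times"); check_num(values, "values")
  check_num(condition, "condition", 1)
  if (length(times) != length(values)) {
    stop_pm("times and values must have the same length", "pm_data_error")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop_pm("times must be strictly increasing", "pm_data_error")
  }
  structure(
    list(times = as.numeric(times), values = as.numeric(values),
         condition = as.numeric(condition),
         condition_name = condition_name, response_units = response_units),
    class = "pm_curve"
  )
}

#' Construct a dataset of curves
#'
#' @param curves list of [pm_curve()] objects sharing `condition_name`
#'   and `response_units`.
#' @param kind `"growth"` or `"inhibition"`.
#' @return An object of class `pm_dataset`.
#' @export
pm_dataset <- function(curves, kind = c("growth", "inhibition")) {
  kind <- match.arg(kind)
  if (!length(curves) || !all(vapply(curves, inherits, TRUE, "pm_curve"))) {
    stop_pm("curves must be a non-empty list of pm_curve objects", "pm_data_error")
  }
  cn <- unique(vapply(curves, `[[`, "", "condition_name"))
  un <- unique(vapply(curves, `[[`, "", "response_units"))
  if (length(cn) != 1L || length(un) != 1L) {
    stop_pm("all curves must share condition_name and response_units",
            "pm_data_error")
  }
  ord <- order(vapply(curves, `[[`, 0, "condition"))
  structure(list(curves = curves[ord], kind = kind,
                 condition_name = cn, response_units = un),
            class = "pm_dataset")
}

#' @export
print.pm_curve <- function(x, ...) {
  cat(sprintf("<pm_curve> %s = %g, %d observations, t in [%g, %g]\n",
              x$condition_name, x$condition, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
print.pm_dataset <- function(x, ...) {
  cat(sprintf("<pm_dataset> kind = %s, %d curve(s), %s in {%s}\n",
              x$kind, length(x$curves), x$condition_name,
              paste(vapply(x$curves, `[[`, 0, "condition"), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.pm_curve <- function(x, ...) {
  data.frame(time = x$times, response = x$values, condition = x$condition)
}

#' @export
as.data.frame.pm_dataset <- function(x, ...) {
  do.call(rbind, lapply(x$curves, as.data.frame))
}

#' @noRd
dataset_conditions <- function(dataset) {
  vapply(dataset$curves, `[[`, 0, "condition")
}
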