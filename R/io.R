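# CSV input, structured reports, and JSON round-tripping.

#' Read curves from a CSV file
#'
#' Expects a header with (at least) a time, response and condition
#' column.  Rows are validated (numeric cells, no duplicated
#' condition/time pairs) and sorted by condition then time before the
#' dataset is assembled, so row order in the file is irrelevant.
#'
#' @param path CSV file path.
#' @param kind `"growth"` or `"inhibition"`.
#' @param time_col,response_col,condition_col column names (defaults
#'   `"time"`, `"response"`, `"condition"`).
#' @param condition_name label of the environmental variable.
#' @param response_units label of the response scale.
#' @return A [pm_dataset()].
#' @export
read_curves <- function(path, kind = c("growth", "inhibition"),
                        time_col = "time", response_col = "response",
                        condition_col = "condition",
                        condition_name = NULL, response_units = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_pm(sprintf("file not found: %s", path),
                                  "pm_io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(time_col, response_col, condition_col)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_pm(sprintf("missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")), "pm_parse_error")
  }
  for (col in need) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad)) {
      stop_pm(sprintf("non-numeric or missing '%s' in row(s): %s",
                      col, paste(bad, collapse = ", ")), "pm_parse_error")
    }
    raw[[col]] <- v
  }
  key <- paste(raw[[condition_col]], raw[[time_col]])
  if (anyDuplicated(key)) {
    stop_pm(sprintf("duplicate (condition, time) pair(s) in row(s): %s",
                    paste(which(duplicated(key)), collapse = ", ")),
            "pm_parse_error")
  }
  raw <- raw[order(raw[[condition_col]], raw[[time_col]]), , drop = FALSE]
  if (is.null(condition_name)) {
    condition_name <- if (kind == "growth") "temperature" else "chlorine"
  }
  if (is.null(response_units)) {
    response_units <- if (kind == "growth") "log10 CFU/g" else "log10 CFU/cm2"
  }
  curves <- lapply(unique(raw[[condition_col]]), function(x) {
    sub <- raw[raw[[condition_col]] == x, , drop = FALSE]
    pm_curve(sub[[time_col]], sub[[response_col]], x,
             condition_name = condition_name,
             response_units = response_units)
  })
  pm_dataset(curves, kind = kind)
}

#' @noRd
fit_to_list <- function(fit) {
  list(model_id = fit$model_id,
       estimates = as.list(fit$estimates),
       std_errors = as.list(fit$std_errors),
       covariance = unname(apply(fit$covariance, 1, as.list)),
       resid_var = fit$resid_var,
       n_obs = fit$n_obs, n_params = fit$n_params,
       rmse = fit$rmse, r2 = fit$r2, sse = fit$sse, sst = fit$sst)
}

#' Assemble a structured analysis report
#'
#' @param results named list of `pm_fit` / `pm_two_step` / `pm_ml`
#'   objects (or plain lists) to serialize.
#' @param seed seed used for the run.
#' @param input_summary optional description of the input data.
#' @param timestamp include a wall-clock timestamp (default FALSE so
#'   identical runs produce byte-identical reports).
#' @return A `pm_report` list.
#' @export
pm_report <- function(results, seed = NULL, input_summary = NULL,
                      timestamp = FALSE) {
  meta <- list(package = "predmicro",
               version = as.character(utils::packageVersion("predmicro")),
               seed = seed)
  if (timestamp) meta$timestamp <- format(Sys.time(), tz = "UTC")
  serial <- lapply(results, function(r) {
    if (inherits(r, "pm_fit")) fit_to_list(r)
    else if (inherits(r, "pm_two_step")) {
      list(model_id = r$model_id, kind = r$kind,
           primary_fits = lapply(r$primary_fits, fit_to_list),
           param_table = as.list(r$param_table),
           secondary_fit = fit_to_list(r$secondary_fit))
    } else if (inherits(r, "pm_ml")) {
      list(algorithm = r$algorithm,
           scaler = list(mean = as.list(r$scaler$mean),
                         sd = as.list(r$scaler$sd)),
           train_rmse = r$train_rmse, train_r2 = r$train_r2,
           test_rmse = r$test_rmse, test_r2 = r$test_r2,
           cv_rmse = r$cv_rmse,
           band = if (!is.null(r$band)) as.list(as.data.frame(r$band)))
    } else if (inherits(r, "pm_band")) {
      as.list(as.data.frame(r))
    } else r
  })
  structure(list(metadata = meta, input = input_summary, results = serial),
            class = "pm_report")
}

#' Write a report to disk
#'
#' JSON preserves the full structure losslessly (numbers at full double
#' precision); CSV flattens the parameter estimates of each result block
#' into a table.
#'
#' @param report a [pm_report()].
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "pm_report"))
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  } else {
    rows <- list()
    for (nm in names(report$results)) {
      r <- report$results[[nm]]
      if (!is.null(r$estimates)) {
        rows[[nm]] <- data.frame(result = nm, model = r$model_id,
                                 parameter = names(r$estimates),
                                 estimate = unlist(r$estimates),
                                 std_error = unlist(r$std_errors))
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(result = character(), model = character(),
                 parameter = character(), estimate = numeric(),
                 std_error = numeric())
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path JSON file written by [write_report()].
#' @return The report as a plain list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}
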