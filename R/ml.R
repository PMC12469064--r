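# Machine-learning workflow: z-score scaling, small-sample augmentation,
# stratified splitting, 5-fold cross-validation, and three regressors
# (GPR, SVR, RFR) on (time, condition) feature pairs.

ML_ALGORITHMS <- c("gpr", "svr", "rfr")

#' Configuration for the machine-learning workflow
#'
#' Defaults follow the reference workflow: training folds with fewer
#' than 750 rows are augmented by resampling with uniform +/-0.2 log10
#' label noise, an 80/20 stratified split, 5-fold cross-validation and
#' 100 bootstrap iterations for non-probabilistic regressors.
#'
#' @param algorithm `"gpr"`, `"svr"` or `"rfr"`.
#' @param augment_threshold training sets below this size are augmented
#'   up to it (default 750).
#' @param augment_noise half-width of the uniform label noise (log10
#'   units, default 0.2).
#' @param test_fraction held-out fraction (default 0.2).
#' @param cv_folds cross-validation folds (default 5).
#' @param bootstrap_iters bootstrap iterations for SVR/RFR bands
#'   (default 100).
#' @param gpr_restarts seeded restarts for GPR hyperparameter search.
#' @param rf_trees trees for the random forest (default 500).
#' @param seed RNG seed.
#' @return A `pm_ml_config` list.
#' @export
ml_config <- function(algorithm = ML_ALGORITHMS, augment_threshold = 750,
                      augment_noise = 0.2, test_fraction = 0.2,
                      cv_folds = 5, bootstrap_iters = 100,
                      gpr_restarts = 5, rf_trees = 500,
                      seed = DEFAULT_SEED) {
  algorithm <- match.arg(algorithm)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_pm("test_fraction must lie in (0, 1)", "pm_domain_error")
  }
  if (cv_folds < 2) stop_pm("cv_folds must be at least 2", "pm_domain_error")
  if (augment_noise < 0) stop_pm("augment_noise must be non-negative",
                                 "pm_domain_error")
  structure(list(algorithm = algorithm, augment_threshold = augment_threshold,
                 augment_noise = augment_noise, test_fraction = test_fraction,
                 cv_folds = cv_folds, bootstrap_iters = bootstrap_iters,
                 gpr_restarts = gpr_restarts, rf_trees = rf_trees,
                 seed = seed),
            class = "pm_ml_config")
}

#' Z-score scaler fitted on training features
#'
#' Columns are centred on their mean and divided by their population
#' standard deviation (denominator n), so scaled training columns have
#' mean 0 and population sd 1.  Constant columns get a unit divisor and
#' scale to all zeros.
#'
#' @param features data frame or matrix of numeric features.
#' @return A `pm_scaler` with `mean` and `sd` per column.
#' @export
zscore_fit <- function(features) {
  X <- as.matrix(features)
  m <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, m)^2))   # population sd
  s[s == 0] <- 1
  structure(list(mean = m, sd = s), class = "pm_scaler")
}

#' @rdname zscore_fit
#' @param scaler a `pm_scaler` from [zscore_fit()].
#' @export
zscore_apply <- function(scaler, features) {
  X <- as.matrix(features)
  sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, "/")
}

#' @rdname zscore_fit
#' @param scaled matrix of scaled features to map back.
#' @export
zscore_invert <- function(scaler, scaled) {
  X <- as.matrix(scaled)
  sweep(sweep(X, 2, scaler$sd, "*"), 2, scaler$mean, "+")
}

#' Augment a small training table by noisy resampling
#'
#' When the training table has fewer rows than the configured threshold,
#' rows are resampled with replacement until the table reaches exactly
#' that size; features are copied unchanged and uniform noise of
#' half-width `augment_noise` is added to the resampled responses.
#' Tables at or above the threshold are returned untouched.  Apply only
#' to training folds, never to held-out data.
#'
#' @param train data frame containing the response column.
#' @param response_col name of the response column.
#' @param config a [ml_config()].
#' @param seed RNG seed.
#' @return The (possibly augmented) data frame.
#' @export
augment_training <- function(train, response_col, config,
                             seed = config$seed) {
  n <- nrow(train)
  if (n >= config$augment_threshold) return(train)
  m <- config$augment_threshold - n
  with_seed(seed, {
    idx <- sample.int(n, m, replace = TRUE)
    extra <- train[idx, , drop = FALSE]
    extra[[response_col]] <- extra[[response_col]] +
      stats::runif(m, -config$augment_noise, config$augment_noise)
    out <- rbind(train, extra)
    rownames(out) <- NULL
    out
  })
}

#' Stratified train/test split on a condition column
#'
#' Samples the test fraction within every condition level so the
#' environmental distribution is preserved across sets; a single level
#' degrades to a plain random split.
#'
#' @param data data frame.
#' @param condition_col column to stratify on.
#' @param test_fraction held-out fraction.
#' @param seed RNG seed.
#' @return List with `train`, `test` and the selected `test_idx`.
#' @export
stratified_split <- function(data, condition_col, test_fraction = 0.2,
                             seed = DEFAULT_SEED) {
  stopifnot(condition_col %in% names(data))
  lev <- data[[condition_col]]
  test_idx <- with_seed(seed, {
    unlist(lapply(unique(lev), function(l) {
      i <- which(lev == l)
      k <- round(test_fraction * length(i))
      if (k == 0) integer(0) else sample(i, k)
    }))
  })
  test_idx <- sort(test_idx)
  list(train = data[setdiff(seq_len(nrow(data)), test_idx), , drop = FALSE],
       test = data[test_idx, , drop = FALSE],
       test_idx = test_idx)
}

# --- regressor backends -------------------------------------------------

# median-heuristic RBF width on scaled features
#' @noRd
median_gamma <- function(X) {
  d2 <- sq_dist(as.matrix(X))
  med <- stats::median(d2[upper.tri(d2)])
  if (!is.finite(med) || med == 0) med <- 1
  1 / med
}

#' @noRd
train_svr <- function(X, y, seed, folds = 5) {
  g0 <- median_gamma(X)
  grid <- expand.grid(cost = c(1, 10, 100), epsilon = c(0.01, 0.1),
                      gamma = g0 * c(0.5, 1, 2))
  n <- nrow(X)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  cv_rmse <- vapply(seq_len(nrow(grid)), function(i) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- e1071::svm(x = X[tr, , drop = FALSE], y = y[tr],
                        type = "eps-regression", kernel = "radial",
                        cost = grid$cost[i], epsilon = grid$epsilon[i],
                        gamma = grid$gamma[i], scale = FALSE)
      pr <- stats::predict(fit, X[!tr, , drop = FALSE])
      sqrt(mean((y[!tr] - pr)^2))
    }, 0)
    mean(errs)
  }, 0)
  bi <- which.min(cv_rmse)
  e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
             cost = grid$cost[bi], epsilon = grid$epsilon[bi],
             gamma = grid$gamma[bi], scale = FALSE)
}

# Trains the requested regressor on scaled features; returns a list with
# a `predict(Xnew)` closure (means only) and the fitted object.
#' @noRd
train_regressor <- function(algorithm, X, y, config, seed = config$seed) {
  X <- as.matrix(X)
  if (algorithm == "gpr") {
    fit <- gpr_fit(X, y, restarts = config$gpr_restarts, seed = seed)
    list(model = fit,
         predict = function(Xn) predict(fit, as.matrix(Xn)),
         predict_se = function(Xn) predict(fit, as.matrix(Xn), se = TRUE))
  } else if (algorithm == "svr") {
    fit <- train_svr(X, y, seed = seed, folds = config$cv_folds)
    list(model = fit,
         predict = function(Xn) as.numeric(stats::predict(fit, as.matrix(Xn))))
  } else {
    fit <- with_seed(seed,
      randomForest::randomForest(x = X, y = y, ntree = config$rf_trees))
    list(model = fit,
         predict = function(Xn) as.numeric(stats::predict(fit, as.matrix(Xn))))
  }
}

# full training-fold pipeline: augment -> scale -> train; returns a
# closure predicting the unscaled response from raw features
#' @noRd
train_pipeline <- function(algorithm, train_df, feature_cols, response_col,
                           config, seed) {
  train_aug <- augment_training(train_df, response_col, config, seed = seed)
  scaler <- zscore_fit(train_aug[feature_cols])
  Xs <- zscore_apply(scaler, train_aug[feature_cols])
  reg <- train_regressor(algorithm, Xs, train_aug[[response_col]], config,
                         seed = seed)
  out <- list(scaler = scaler, regressor = reg,
              predict = function(newdf) {
                reg$predict(zscore_apply(scaler, newdf[feature_cols]))
              })
  if (!is.null(reg$predict_se)) {
    out$predict_se <- function(newdf) {
      reg$predict_se(zscore_apply(scaler, newdf[feature_cols]))
    }
  }
  out
}

#' k-fold cross-validation of an ML pipeline
#'
#' Observations are partitioned into `folds` validation folds (each row
#' appears in exactly one).  Within every iteration the full
#' preprocessing pipeline (augmentation, scaling) is re-derived from the
#' training folds only, the regressor is trained and the validation fold
#' scored by RMSE (denominator n).
#'
#' @param algorithm `"gpr"`, `"svr"` or `"rfr"`.
#' @param data data frame of features plus response.
#' @param feature_cols names of the feature columns.
#' @param response_col name of the response column.
#' @param folds number of folds (default 5).
#' @param seed RNG seed.
#' @param config a [ml_config()].
#' @return List with `fold_rmse`, the across-fold mean `cv_rmse`, and
#'   `fold_id`.
#' @export
cross_validate <- function(algorithm, data, feature_cols, response_col,
                           folds = 5, seed = DEFAULT_SEED,
                           config = ml_config(algorithm, seed = seed)) {
  n <- nrow(data)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  fold_rmse <- vapply(seq_len(folds), function(f) {
    tr <- data[fold_id != f, , drop = FALSE]
    va <- data[fold_id == f, , drop = FALSE]
    pipe <- train_pipeline(algorithm, tr, feature_cols, response_col,
                           config, seed = seed + f)
    rmse(va[[response_col]], pipe$predict(va), s = 0)
  }, 0)
  list(fold_rmse = fold_rmse, cv_rmse = mean(fold_rmse), fold_id = fold_id)
}

#' Fit a machine-learning regressor on a (time, condition) dataset
#'
#' Full data-driven workflow: canonical row ordering, stratified 80/20
#' split on the condition column, augmentation of the training rows when
#' below the configured threshold, z-score scaling fitted on the
#' (augmented) training features only, regressor training, train/test
#' metrics on the unscaled response, optional 5-fold cross-validation on
#' the training rows, and a 95% band at the test points (analytic for
#' GPR as mean +/- 1.96 sigma; percentile bootstrap with B refits for
#' SVR/RFR).
#'
#' @param features data frame with exactly two columns: time and one
#'   environmental condition (in that order).
#' @param response numeric log10 counts, one per feature row.
#' @param config a [ml_config()]; its `algorithm` selects the regressor.
#' @param compute_cv run cross-validation (default TRUE).
#' @param compute_band compute the 95% band at the test points
#'   (default TRUE).
#' @return A `pm_ml` object with the trained pipeline, metrics and band.
#' @export
fit_ml <- function(features, response, config = ml_config("gpr"),
                   compute_cv = TRUE, compute_band = TRUE) {
  stopifnot(inherits(config, "pm_ml_config"))
  features <- as.data.frame(features)
  if (ncol(features) != 2) {
    stop_pm("the ML workflow takes exactly two features (time + one condition)",
            "pm_data_error")
  }
  check_num(response, "response", nrow(features))
  if (nrow(features) < 10) {
    stop_pm("need at least 10 observations for ML fitting", "pm_data_error")
  }
  feature_cols <- names(features)
  cond_col <- feature_cols[2]
  df <- cbind(features, .response = response)
  # canonical order makes the whole pipeline row-order invariant
  df <- df[order(df[[cond_col]], df[[feature_cols[1]]], df$.response), ,
           drop = FALSE]
  rownames(df) <- NULL
  sp <- stratified_split(df, cond_col, config$test_fraction, config$seed)
  pipe <- train_pipeline(config$algorithm, sp$train, feature_cols,
                         ".response", config, seed = config$seed)
  pred_train <- pipe$predict(sp$train)
  pred_test <- pipe$predict(sp$test)
  cv <- if (compute_cv) {
    cross_validate(config$algorithm, sp$train, feature_cols, ".response",
                   folds = config$cv_folds, seed = config$seed,
                   config = config)
  } else NULL
  band <- NULL
  if (compute_band) {
    if (config$algorithm == "gpr") {
      gp_test <- pipe$predict_se(sp$test)
      band <- new_band(sp$test[[feature_cols[1]]], gp_test$mean, gp_test$sd,
                       gp_test$mean - 1.96 * gp_test$sd,
                       gp_test$mean + 1.96 * gp_test$sd,
                       method = "gpr analytic")
    } else {
      test_feat <- sp$test[feature_cols]
      band <- bootstrap_band(
        function(d) {
          p <- train_pipeline(config$algorithm, d, feature_cols, ".response",
                              config, seed = config$seed)
          function(q) p$predict(q)
        },
        sp$train, test_feat, B = config$bootstrap_iters, seed = config$seed)
    }
  }
  structure(list(
    algorithm = config$algorithm, config = config,
    scaler = pipe$scaler, model = pipe$regressor$model,
    pipeline = pipe, split = sp,
    train_rmse = rmse(sp$train$.response, pred_train, s = 0),
    train_r2 = r_squared(sp$train$.response, pred_train),
    test_rmse = rmse(sp$test$.response, pred_test, s = 0),
    test_r2 = r_squared(sp$test$.response, pred_test),
    cv_rmse = if (is.null(cv)) NA_real_ else cv$cv_rmse,
    cv = cv, band = band
  ), class = "pm_ml")
}

#' @export
print.pm_ml <- function(x, ...) {
  cat(sprintf("<pm_ml> %s: train RMSE %.4g (R2 %.4g), test RMSE %.4g (R2 %.4g)",
              toupper(x$algorithm), x$train_rmse, x$train_r2,
              x$test_rmse, x$test_r2))
  if (!is.na(x$cv_rmse)) cat(sprintf(", CV RMSE %.4g", x$cv_rmse))
  cat("\n")
  invisible(x)
}

#' Predict from a fitted ML pipeline
#' @param object a `pm_ml` fit.
#' @param newdata data frame with the two feature columns.
#' @param ... unused.
#' @export
predict.pm_ml <- function(object, newdata, ...) {
  object$pipeline$predict(as.data.frame(newdata))
}
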