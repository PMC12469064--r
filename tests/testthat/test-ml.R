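# ML workflow: scaling, augmentation, splitting, cross-validation,
# regressors, leakage and determinism.

test_that("z-score scaling uses the population standard deviation", {
  sc <- zscore_fit(data.frame(a = c(1, 2, 3)))
  scaled <- zscore_apply(sc, data.frame(a = c(1, 2, 3)))
  expect_equal(as.numeric(scaled), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  expect_equal(as.numeric(scaled)[1], -1.22474487139159, tolerance = 1e-10)
  # constant columns scale to zeros with a guarded divisor
  sc2 <- zscore_fit(data.frame(a = rep(4, 5)))
  expect_equal(as.numeric(zscore_apply(sc2, data.frame(a = rep(4, 5)))),
               rep(0, 5))
  # round trip is the identity
  X <- data.frame(a = rnorm(10), b = runif(10))
  sc3 <- zscore_fit(X)
  expect_equal(zscore_invert(sc3, zscore_apply(sc3, X)), as.matrix(X),
               tolerance = 1e-12)
})

test_that("augmentation fills small training tables to the threshold", {
  cfg <- ml_config("rfr", augment_threshold = 750, seed = 1)
  train <- data.frame(time = 1:10, condition = rep(c(4, 10), 5),
                      y = rnorm(10))
  aug <- augment_training(train, "y", cfg, seed = 1)
  expect_equal(nrow(aug), 750)
  # original rows preserved at the head
  expect_equal(aug[1:10, c("time", "condition")],
               train[, c("time", "condition")])
  # every added response within the noise half-width of its source row
  added <- aug[11:750, ]
  src <- train[match(paste(added$time, added$condition),
                     paste(train$time, train$condition)), ]
  expect_true(all(abs(added$y - src$y) <= 0.2 + 1e-12))
  # features copied unchanged: all rows exist in the original design
  expect_true(all(paste(added$time, added$condition) %in%
                    paste(train$time, train$condition)))
  # disabled at or above the threshold
  cfg2 <- ml_config("rfr", augment_threshold = 10, seed = 1)
  expect_identical(augment_training(train, "y", cfg2, seed = 1), train)
})

test_that("stratified split preserves per-condition proportions", {
  df <- data.frame(condition = rep(c(4, 10), each = 50), y = rnorm(100))
  sp <- stratified_split(df, "condition", 0.2, seed = 3)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_equal(as.numeric(table(sp$test$condition)), c(10, 10))
  expect_equal(as.numeric(table(sp$train$condition)), c(40, 40))
  # reproducible under the seed, disjoint and exhaustive
  sp2 <- stratified_split(df, "condition", 0.2, seed = 3)
  expect_identical(sp$test_idx, sp2$test_idx)
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0)
  # single condition degrades to a plain split
  df1 <- data.frame(condition = rep(1, 40), y = rnorm(40))
  sp1 <- stratified_split(df1, "condition", 0.2, seed = 3)
  expect_equal(nrow(sp1$test), 8)
})

test_that("cross-validation partitions every row exactly once", {
  df <- ml_growth_df(5)
  cv <- cross_validate("rfr", cbind(df, .response = df$response),
                       c("time", "condition"), ".response",
                       folds = 5, seed = 2,
                       config = ml_config("rfr", augment_threshold = 1,
                                          rf_trees = 100, seed = 2))
  expect_length(cv$fold_id, nrow(df))
  expect_equal(sort(unique(cv$fold_id)), 1:5)
  expect_equal(cv$cv_rmse, mean(cv$fold_rmse))
  expect_true(all(cv$fold_rmse > 0))
})

test_that("GPR nearly interpolates noise-free smooth data", {
  set.seed(6)
  x <- matrix(seq(-3, 3, length.out = 30))
  y <- 5 / (1 + exp(-2 * x[, 1]))
  fit <- gpr_fit(x, y, restarts = 3, seed = 6)
  pr <- predict(fit, x)
  expect_lt(sqrt(mean((y - pr)^2)), 1e-2)
})

test_that("GPR agrees with an independent GP implementation on a fixture", {
  skip_if_not_installed("kernlab")
  set.seed(14)
  x <- matrix(seq(0, 10, length.out = 40))
  y <- sin(x[, 1]) + rnorm(40, 0, 0.05)
  ours <- gpr_fit(x, y, restarts = 3, seed = 14)
  # kernlab with the hyperparameters our marginal likelihood selected
  kl <- kernlab::gausspr(x, y, kernel = "rbfdot",
                         kpar = list(sigma = 1 / (2 * ours$ell2)),
                         var = ours$sigma_n2 + 1e-8, scaled = FALSE,
                         variance.model = FALSE)
  # posterior means of the same GP model should agree closely
  xq <- matrix(seq(0.5, 9.5, length.out = 15))
  expect_equal(as.numeric(kernlab::predict(kl, xq)),
               predict(ours, xq), tolerance = 0.05)
})

test_that("GPR analytic band covers held-out noise-free truth", {
  cover <- sapply(1:3, function(r) {
    df <- ml_growth_df(300 + r)
    f <- fit_ml(df[c("time", "condition")], df$response,
                ml_config("gpr", seed = 300 + r),
                compute_cv = FALSE, compute_band = TRUE)
    truth <- sapply(seq_len(nrow(f$split$test)), function(i) {
      X <- f$split$test$condition[i]
      mu <- ratkowsky_mu(X, 0.0014, -9.24)
      growth_baranyi(f$split$test$time[i], 3.5, 9.5, mu, 1.29 / mu)
    })
    c(hits = sum(truth >= f$band$lower & truth <= f$band$upper),
      n = length(truth))
  })
  expect_gte(sum(cover["hits", ]) / sum(cover["n", ]), 0.85)
})

test_that("the pipeline derives nothing from test rows", {
  df <- ml_growth_df(9)
  cfg <- ml_config("rfr", rf_trees = 100, seed = 9)
  f <- fit_ml(df[c("time", "condition")], df$response, cfg,
              compute_cv = FALSE, compute_band = FALSE)
  # scaler equals one fitted on the augmented training rows alone
  tr_aug <- augment_training(f$split$train, ".response", cfg, seed = cfg$seed)
  sc <- zscore_fit(tr_aug[c("time", "condition")])
  expect_equal(f$scaler$mean, sc$mean)
  expect_equal(f$scaler$sd, sc$sd)
  # corrupting the test responses changes no trained prediction
  df2 <- df
  test_rows <- match(paste(f$split$test$time, f$split$test$condition),
                     paste(df2$time, df2$condition))
  df2$response[test_rows] <- df2$response[test_rows] + 100
  f2 <- fit_ml(df2[c("time", "condition")], df2$response, cfg,
               compute_cv = FALSE, compute_band = FALSE)
  grid <- data.frame(time = c(10, 30, 60), condition = c(4, 10, 20))
  expect_equal(predict(f, grid), predict(f2, grid))
})

test_that("pipeline metrics are invariant to row order", {
  df <- ml_growth_df(13)
  cfg <- ml_config("rfr", rf_trees = 100, seed = 13)
  f1 <- fit_ml(df[c("time", "condition")], df$response, cfg,
               compute_cv = FALSE, compute_band = FALSE)
  set.seed(1); perm <- sample(nrow(df))
  f2 <- fit_ml(df[perm, c("time", "condition")], df$response[perm], cfg,
               compute_cv = FALSE, compute_band = FALSE)
  expect_identical(f1$train_rmse, f2$train_rmse)
  expect_identical(f1$test_rmse, f2$test_rmse)
})

test_that("seeded ML fits are bitwise reproducible", {
  df <- ml_growth_df(23)
  grid <- data.frame(time = seq(5, 60, by = 5), condition = 10)
  for (alg in c("svr", "rfr")) {
    cfg <- ml_config(alg, rf_trees = 100, bootstrap_iters = 10, seed = 23)
    f1 <- fit_ml(df[c("time", "condition")], df$response, cfg,
                 compute_cv = FALSE, compute_band = TRUE)
    f2 <- fit_ml(df[c("time", "condition")], df$response, cfg,
                 compute_cv = FALSE, compute_band = TRUE)
    expect_identical(predict(f1, grid), predict(f2, grid), info = alg)
    expect_identical(f1$band$lower, f2$band$lower, info = alg)
    expect_identical(f1$test_rmse, f2$test_rmse, info = alg)
  }
})

test_that("undersized or malformed feature tables are refused", {
  expect_error(fit_ml(data.frame(t = 1:5, c = 1:5), rnorm(5),
                      ml_config("rfr")), "at least 10")
  expect_error(fit_ml(data.frame(t = 1:20), rnorm(20), ml_config("rfr")),
               "two features")
})
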