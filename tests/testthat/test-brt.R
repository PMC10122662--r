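# the Poisson boosted-tree engine: CV selection, influence, partial
# dependence, interactions, rerun aggregation and Moran's I

make_planted <- function(n = 600, p_noise = 4, beta = 0.8, seed = 1) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * (p_noise + 1)), n))
  names(X) <- paste0("x", seq_len(p_noise + 1))
  X$y <- rpois(n, exp(1 + beta * X$x1))
  X
}

test_that("constant response gives ~zero CV-D2 and constant predictions", {
  set.seed(2)
  d <- data.frame(x1 = rnorm(200), x2 = rnorm(200), y = rep(3L, 200))
  fit <- fit_brt(d, "y", small_brt_params(), seed = 1)
  expect_lte(fit$cv_D2, 0.05)
  expect_lt(diff(range(predict(fit))), 0.2)
  expect_equal(sum(fit$relative_influence$influence), 100, tolerance = 1e-6)
})

test_that("a planted predictor dominates the relative influence", {
  d <- make_planted(n = 800, seed = 3)
  fit <- fit_brt(d, "y", small_brt_params(), seed = 4)
  ri <- fit$relative_influence
  expect_equal(ri$predictor[1], "x1")
  expect_gt(ri$influence[1], 50)
  expect_gt(fit$cv_D2, 0.3)
  # training deviance never exceeds the null deviance
  expect_lte(fit$train_deviance, fit$null_deviance)
})

test_that("pure-noise predictors give CV-D2 near zero", {
  set.seed(5)
  d <- as.data.frame(matrix(rnorm(1000 * 10), 1000))
  names(d) <- paste0("x", 1:10)
  d$y <- rpois(1000, 2)
  fit <- fit_brt(d, "y", small_brt_params(), seed = 6)
  expect_gt(fit$cv_D2, -0.1)
  expect_lt(fit$cv_D2, 0.1)
})

test_that("predictions are invariant to predictor column order", {
  d <- make_planted(n = 300, seed = 7)
  fit1 <- fit_brt(d, "y", small_brt_params(), seed = 8)
  d2 <- d[, c("x3", "x1", "x5", "x2", "x4", "y")]
  fit2 <- fit_brt(d2, "y", small_brt_params(), seed = 8)
  # same seed, same rows: the fitted ensembles see identical bags
  expect_equal(predict(fit1, d), predict(fit2, d), tolerance = 1e-9)
})

test_that("response validation and warnings behave", {
  d <- data.frame(x = rnorm(50), y = rnorm(50))
  expect_error(fit_brt(d, "y", small_brt_params()), "counts")
  d$y <- rpois(50, 2)
  d$x[1] <- NA
  expect_error(fit_brt(d, "y", small_brt_params()), "missing")
  # strong signal with a tiny tree budget: curve still falling at max_trees
  d2 <- make_planted(n = 400, seed = 9)
  expect_warning(
    fit <- fit_brt(d2, "y", brt_params(learning_rate = 0.01, max_trees = 20,
                                       step_size = 10, n_folds = 3,
                                       patience = 3), seed = 1),
    "max_trees")
  expect_equal(fit$nt, 20)
})

test_that("relative influence: unused predictors get zero, sum is 100", {
  d <- make_planted(n = 500, beta = 1.2, seed = 10)
  d$konst <- 1  # constant: can never be split on
  fit <- fit_brt(d, "y", small_brt_params(), seed = 11)
  ri <- fit$relative_influence
  expect_equal(ri$influence[ri$predictor == "konst"], 0)
  expect_equal(sum(ri$influence), 100, tolerance = 1e-6)
})

test_that("duplicated informative predictors share the single-copy influence", {
  set.seed(12)
  n <- 1200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- rpois(n, exp(0.8 + 0.9 * d$x1))
  fit1 <- fit_brt(d, "y", small_brt_params(), seed = 13)
  single <- fit1$relative_influence$influence[
    fit1$relative_influence$predictor == "x1"]
  d$x1dup <- d$x1
  fit2 <- fit_brt(d, "y", small_brt_params(), seed = 13)
  ri2 <- fit2$relative_influence
  combined <- sum(ri2$influence[ri2$predictor %in% c("x1", "x1dup")])
  expect_equal(combined, single, tolerance = 5)
})

test_that("partial dependence recovers the planted monotone sign", {
  d <- make_planted(n = 600, beta = 0.8, seed = 14)
  fit <- fit_brt(d, "y", small_brt_params(), seed = 15)
  pd <- partial_dependence(fit, "x1", grid = 15)
  expect_gt(cor(pd$value, pd$yhat, method = "spearman"), 0.9)
  expect_error(partial_dependence(fit, "nope"), "not in the model")
  # a zero-influence predictor has an essentially flat curve
  d$konst <- 1
  fit2 <- fit_brt(d, "y", small_brt_params(), seed = 15)
  pdk <- partial_dependence(fit2, "konst")
  expect_lt(diff(range(pdk$yhat)), 1e-6 * mean(pdk$yhat) + 1e-12)
})

test_that("partial dependence at a clamped value equals the clamped mean prediction", {
  d <- make_planted(n = 300, seed = 16)
  fit <- fit_brt(d, "y", small_brt_params(), seed = 17)
  v <- median(d$x1)
  pd <- invasispace:::pd_compute(fit, "x1", v, seq_len(nrow(d)))
  clamped <- d
  clamped$x1 <- v
  expect_equal(pd, mean(predict(fit, clamped)), tolerance = 1e-10)
})

test_that("interaction strength is symmetric and flags the planted product", {
  set.seed(18)
  n <- 500
  d <- as.data.frame(matrix(rnorm(n * 4), n))
  names(d) <- paste0("x", 1:4)
  d$y <- rpois(n, exp(0.4 + 0.6 * d$x1 * d$x2))
  fit <- fit_brt(d, "y", small_brt_params(), seed = 19)
  s12 <- interaction_strength(fit, "x1", "x2")
  s21 <- interaction_strength(fit, "x2", "x1")
  expect_equal(s12, s21, tolerance = 1e-10)
  m <- interaction_matrix(fit)
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(diag(unclass(m)) == 0))
  off <- unclass(m)
  expect_equal(max(off), off["x1", "x2"])
  # constant predictor: degenerate grid, zero strength
  d$konst <- 1
  fit2 <- fit_brt(d, "y", small_brt_params(), seed = 19)
  expect_equal(interaction_strength(fit2, "x1", "konst"), 0)
})

test_that("rerun_aggregate means are consistent and reproducible", {
  d <- make_planted(n = 400, seed = 20)
  agg1 <- rerun_aggregate(d, "y", small_brt_params(), n_runs = 1,
                          base_seed = 21)
  single <- fit_brt(d, "y", small_brt_params(),
                    seed = invasispace:::derive_seed(21, 1))
  expect_equal(agg1$mean_cv_D2, single$cv_D2)
  expect_equal(sum(agg1$mean_influence$mean_influence), 100,
               tolerance = 1e-6)
  agg3 <- rerun_aggregate(d, "y", small_brt_params(), n_runs = 3,
                          base_seed = 21,
                          pd_predictors = "x1", pd_grid = 10, pd_sample = 100)
  expect_equal(sum(agg3$mean_influence$mean_influence), 100,
               tolerance = 1e-6)
  expect_gt(agg3$pd_trends$mean_pd_spearman[1], 0.5)
  expect_equal(agg3$mean_influence$predictor[1], "x1")
})

test_that("an independent boosting implementation agrees on the dominant predictor", {
  skip_if_not_installed("xgboost")
  d <- make_planted(n = 800, p_noise = 5, seed = 30)
  fit <- fit_brt(d, "y", small_brt_params(), seed = 31)
  xm <- as.matrix(d[paste0("x", 1:6)])
  xfit <- xgboost::xgboost(xm, d$y, nrounds = 100,
                           objective = "count:poisson", max_depth = 3,
                           learning_rate = 0.1, nthreads = 1, verbosity = 0)
  imp <- xgboost::xgb.importance(model = xfit)
  expect_equal(fit$relative_influence$predictor[1], imp$Feature[1])
  expect_equal(imp$Feature[1], "x1")
})

test_that("boosting equivalence: scaling lr against nt barely moves CV-D2", {
  d <- make_planted(n = 600, seed = 22)
  f1 <- fit_brt(d, "y", brt_params(learning_rate = 0.1, max_trees = 100,
                                   step_size = 100, n_folds = 4,
                                   patience = 10), seed = 23)
  f2 <- fit_brt(d, "y", brt_params(learning_rate = 0.05, max_trees = 200,
                                   step_size = 200, n_folds = 4,
                                   patience = 10), seed = 23)
  expect_lt(abs(f1$cv_D2 - f2$cv_D2), 0.05)
})

test_that("Moran's I: expectation, hand structure, ape cross-check", {
  set.seed(24)
  n <- 101
  W <- matrix(runif(n * n), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  r <- rnorm(n)
  mi <- morans_i(r, W)
  expect_equal(mi$expectation, -0.01)
  # ape row-normalizes the weights internally; feed ours the same matrix
  ref <- ape::Moran.I(r, W)
  mi_rn <- morans_i(r, W / rowSums(W))
  expect_equal(mi_rn$statistic, ref$observed, tolerance = 1e-10)

  # a smooth gradient on a chain graph is positively autocorrelated
  n2 <- 40
  Wc <- matrix(0, n2, n2)
  for (i in 1:(n2 - 1)) {
    Wc[i, i + 1] <- 1
    Wc[i + 1, i] <- 1
  }
  grad <- seq(0, 1, length.out = n2) + rnorm(n2, 0, 0.05)
  mg <- morans_i(grad, Wc, n_perm = 199, seed = 1)
  expect_gt(mg$statistic, 0.5)
  expect_lt(mg$p_value, 0.05)
  expect_error(morans_i(r, W * 0), "positive weights")
  expect_error(morans_i(r, -W), "nonnegative")
})

test_that("weight matrices round-trip through triplets", {
  tr <- data.frame(i = c("a", "b"), j = c("b", "c"), w = c(1, 2))
  W <- weight_matrix_from_triplets(tr)
  expect_equal(W["a", "b"], 1)
  expect_equal(W["b", "c"], 2)
  expect_equal(W["c", "a"], 0)
  expect_error(weight_matrix_from_triplets(data.frame(x = 1)), "i, j, w")
})
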