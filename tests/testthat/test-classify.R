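make_blobs_xy <- function(n = 100, sep = 2, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n, sep, 0.5), n / 2, 2),
             matrix(rnorm(n, -sep, 0.5), n / 2, 2))
  list(x = x, y = rep(c(1, 0), each = n / 2))
}

test_that("classifiers separate well-separated blobs", {
  d <- make_blobs_xy()
  m1 <- train_mlp_single(d$x, d$y, seed = 7)
  expect_gte(mean(predict(m1, d$x) == d$y), 0.95)
  ms <- train_svm(d$x, d$y)
  expect_gte(mean(predict(ms, d$x) == d$y), 0.95)
})

test_that("constant features collapse to the majority class", {
  x <- matrix(1, 60, 3)
  y <- c(rep(0, 40), rep(1, 20))
  m <- train_mlp_single(x, y, seed = 2)
  expect_true(all(predict(m, matrix(1, 5, 3)) == 0))
})

test_that("training is reproducible under a fixed seed", {
  d <- make_blobs_xy()
  m1 <- train_mlp_single(d$x, d$y, seed = 5)
  m2 <- train_mlp_single(d$x, d$y, seed = 5)
  expect_identical(m1$W1, m2$W1)
  expect_identical(predict(m1, d$x, type = "prob"),
                   predict(m2, d$x, type = "prob"))
  m3 <- train_mlp_multi(d$x, d$y, seed = 5)
  m4 <- train_mlp_multi(d$x, d$y, seed = 5)
  expect_identical(m3$W, m4$W)
})

test_that("single-class training sets are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(train_mlp_single(x, rep(1, 10)), "single class")
  expect_error(train_mlp_multi(x, rep(0, 10)), "single class")
  expect_error(train_svm(x, rep(1, 10)), "single class")
})

test_that("softmax probabilities sum to one for every sample", {
  d <- make_blobs_xy()
  m <- train_mlp_multi(d$x, d$y, seed = 3)
  p <- predict_proba(m, d$x)
  expect_equal(rowSums(p), rep(1, nrow(p)))
  expect_true(all(p >= 0))
})

test_that("hidden layers give the capacity a linear model lacks (XOR)", {
  set.seed(1)
  x <- matrix(runif(200, -1, 1), 100, 2)
  y <- as.integer(x[, 1] * x[, 2] > 0)
  m <- train_mlp_multi(x, y, seed = 1)
  expect_gte(mean(predict(m, x) == y), 0.9)
  base <- stats::glm(y ~ x, family = stats::binomial)
  expect_lt(mean((stats::fitted(base) > 0.5) == y), 0.7)
})

test_that("the polynomial kernel matches its closed form", {
  # (gamma <x,y> + coef0)^3 for x=(1,2), y=(3,-1), gamma=0.5, coef0=1:
  # (0.5 * 1 + 1)^3 = 3.375
  expect_equal(poly_kernel(c(1, 2), c(3, -1), degree = 3, gamma = 0.5,
                           coef0 = 1), 3.375)
  expect_equal(poly_kernel(c(2, 0), c(1, 5), degree = 3, gamma = 1 / 2,
                           coef0 = 0), 1)
})

test_that("flipping all labels flips all SVM predictions", {
  d <- make_blobs_xy(seed = 9)
  m <- train_svm(d$x, d$y)
  mf <- train_svm(d$x, 1 - d$y)
  expect_equal(predict(mf, d$x), 1L - predict(m, d$x))
})

test_that("metrics follow their confusion-matrix definitions", {
  got <- metrics_from_confusion(tp = 8, fp = 2, fn = 1, tn = 9)
  sens <- 8 / 9; spec <- 9 / 11
  prec <- mean(c(8 / 10, 9 / 10))
  rec <- mean(c(sens, spec))
  expect_equal(unname(got["sensitivity"]), sens)
  expect_equal(unname(got["specificity"]), spec)
  expect_equal(unname(got["precision"]), prec)
  expect_equal(unname(got["recall"]), rec)
  expect_equal(unname(got["f1"]), 2 * prec * rec / (prec + rec))
  # empty denominators yield NA, not crashes
  none_pred_pos <- metrics_from_confusion(0, 0, 3, 7)
  expect_true(is.na(none_pred_pos[["precision"]]))
  expect_equal(unname(none_pred_pos["sensitivity"]), 0)
  expect_equal(unname(none_pred_pos["specificity"]), 1)
})

test_that("a leaked label feature drives all metrics to 1", {
  set.seed(8)
  y <- rep(c(0, 1), 30)
  x <- cbind(y, matrix(rnorm(120), 60, 2))
  rep1 <- cross_validate(x, y, classifier_config("svm", n_runs = 2, seed = 3))
  expect_equal(unname(rep1$metrics), rep(1, 5))
})

test_that("random balanced labels give chance-level f1", {
  set.seed(12)
  x <- matrix(rnorm(600), 60, 10)
  y <- rep(c(0, 1), 30)
  rep1 <- cross_validate(x, y, classifier_config("svm", n_runs = 10,
                                                 seed = 5))
  expect_gt(rep1$metrics[["f1"]], 0.4)
  expect_lt(rep1$metrics[["f1"]], 0.6)
})

test_that("reported means re-derive exactly from the per-fold table", {
  d <- make_blobs_xy(seed = 4)
  rep1 <- cross_validate(d$x, d$y,
                         classifier_config("svm", n_runs = 2, seed = 11))
  for (mc in c("precision", "recall", "sensitivity", "specificity", "f1"))
    expect_equal(rep1$metrics[[mc]], mean(rep1$per_fold[[mc]], na.rm = TRUE),
                 tolerance = 1e-12)
  expect_equal(nrow(rep1$per_fold), 2 * 10)
  # confusion counts cover every test sample exactly once per run
  expect_equal(sum(rep1$per_fold[, c("tp", "fp", "fn", "tn")]),
               2 * nrow(d$x))
})

test_that("cross-validation is reproducible and stratified under imbalance", {
  y <- rep(c(0, 1), c(160, 40))
  set.seed(2)
  x <- cbind(y + rnorm(200, sd = 0.1), matrix(rnorm(400), 200, 2))
  cfg <- classifier_config("svm", n_runs = 2, seed = 9)
  r1 <- cross_validate(x, y, cfg)
  r2 <- cross_validate(x, y, cfg)
  expect_identical(r1$metrics, r2$metrics)
  # stratification: every fold's test split contains both classes
  expect_true(all(r1$per_fold$tp + r1$per_fold$fn > 0))
  expect_true(all(r1$per_fold$tn + r1$per_fold$fp > 0))
  expect_error(cross_validate(x[1:12, ], y[c(1:6, 161:166)],
                              classifier_config("svm")), "stratified")
})
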