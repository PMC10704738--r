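test_that("train/test split sizes and partition algebra are exact", {
  X <- matrix(rnorm(19280 * 2), 19280, 2)
  sp <- split_train_test(X, rnorm(19280), test_fraction = 0.10, seed = 1)
  expect_equal(nrow(sp$test$X), 1928)
  expect_equal(nrow(sp$train$X), 17352)

  X2 <- matrix(rnorm(2 * 2), 2, 2)
  sp2 <- split_train_test(X2, rnorm(2), 0.5, seed = 1)
  expect_equal(nrow(sp2$train$X), 1)
  expect_equal(nrow(sp2$test$X), 1)

  Xs <- matrix(rnorm(500), 500, 1)
  ys <- rnorm(500)
  for (s in 1:100) {
    sp3 <- split_train_test(Xs, ys, 0.2, seed = s)
    expect_identical(sort(c(sp3$train$idx, sp3$test$idx)), 1:500)
    expect_length(intersect(sp3$train$idx, sp3$test$idx), 0)
  }
  expect_error(split_train_test(Xs, ys, 1e-9, seed = 1), "empty")
})

test_that("evaluation metrics match closed-form worked examples", {
  m <- evaluate_predictions(c(1, 2, 3), c(2, 2, 2), threshold = 10)
  expect_equal(m$rmse, sqrt(2 / 3))

  y <- c(5, 5, 3, 3, 5)
  m2 <- evaluate_predictions(y, y, threshold = 4.67)
  expect_equal(m2$rmse, 0)
  expect_equal(m2$precision, 1)
  expect_equal(m2$recall, 1)
  expect_equal(m2$f_measure, 1)

  # TP=2 FP=1 FN=0 at threshold 4.67
  m3 <- evaluate_predictions(c(5, 5, 3, 3), c(5, 5, 5, 3), threshold = 4.67)
  expect_equal(m3$precision, 2 / 3)
  expect_equal(m3$recall, 1)
  expect_equal(m3$f_measure, 0.8)
  expect_error(evaluate_predictions(1:3, 1:4), "equal length")
})

test_that("undefined metric ratios are flagged null rather than zeroed", {
  m <- evaluate_predictions(c(1, 2), c(1, 2), threshold = 10)
  expect_true(is.na(m$precision))
  expect_true(is.na(m$recall))
  expect_setequal(m$undefined, c("precision", "recall", "f_measure"))
})

test_that("F-measure is the harmonic mean; RMSE is order-invariant and scales linearly", {
  for (s in 1:20) {
    set.seed(s)
    y <- rnorm(60, mean = 4.67, sd = 1)
    p <- y + rnorm(60, sd = 0.5)
    m <- evaluate_predictions(y, p)
    if (!is.na(m$f_measure)) {
      expect_equal(m$f_measure,
                   2 * m$precision * m$recall / (m$precision + m$recall),
                   tolerance = 1e-9)
    }
    perm <- sample(60)
    expect_equal(evaluate_predictions(y[perm], p[perm])$rmse, m$rmse)
    expect_equal(evaluate_predictions(3 * y, 3 * p)$rmse, 3 * m$rmse)
  }
})

test_that("the network drives training error to near zero on a noiseless linear signal", {
  set.seed(10)
  X <- matrix(rnorm(4000 * 5), 4000, 5, dimnames = list(NULL, paste0("f", 1:5)))
  s <- as.vector(X %*% c(1, -2, 0.5, 1.5, -1))
  y <- 3.4 + 0.5 * (s - mean(s)) / sd(s)
  m <- train_ros_model(X, y, dnn_config(seed = 1L))
  expect_lt(sqrt(mean((y - predict(m, X))^2)), 0.05)
  expect_true(all(is.finite(m$fit$loss_trace)))
  expect_length(m$fit$loss_trace, 100)
})

test_that("both regressor kinds are seeded-reproducible", {
  set.seed(11)
  X <- matrix(rnorm(400 * 4), 400, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 1] - X[, 2]^2 + rnorm(400, sd = 0.1)
  for (cfg in list(dnn_config(hidden_sizes = c(16, 8), epochs = 15, seed = 3),
                   rf_config(seed = 3))) {
    m1 <- train_ros_model(X, y, cfg)
    m2 <- train_ros_model(X, y, cfg)
    expect_identical(predict(m1, X), predict(m2, X))
  }
})

test_that("predictions are chunk-invariant and duplicate-consistent", {
  set.seed(12)
  X <- matrix(rnorm(500 * 6), 500, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- X[, 1] + rnorm(500, sd = 0.1)
  m <- train_ros_model(X, y, dnn_config(hidden_sizes = c(16, 8), epochs = 10))
  whole <- predict(m, X)
  rowwise <- vapply(seq_len(nrow(X)),
                    function(i) predict(m, X[i, , drop = FALSE]), 0)
  expect_equal(rowwise, whole, tolerance = 1e-6)
  dup <- X[c(7, 7), , drop = FALSE]
  p <- predict(m, dup)
  expect_identical(p[1], p[2])
})

test_that("feature-width mismatches are reported by name", {
  set.seed(13)
  X <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- train_ros_model(X, rnorm(100), rf_config())
  expect_error(predict(m, X[, c("a", "b")]), "missing features: c")
  # extra columns are fine; order is fixed by name
  X4 <- cbind(X[, c("c", "a", "b")], d = rnorm(100))
  expect_equal(predict(m, X4), predict(m, X))
})

test_that("predictions recover the planted activity ordering on fresh compounds", {
  spec <- synthetic_spec(n_compounds = 3000, n_features = 50,
                         n_informative = 8, seed = 17L)
  lib <- generate_library(spec)
  tr <- planted_truth(lib)
  scr <- generate_screen_table(lib, 800, seed = 18L)
  m <- train_ros_model(lib$descriptors, lib$log_ros, rf_config())
  pred <- predict(m, scr$descriptors)
  expect_gt(cor(pred, tr$f(scr$descriptors), method = "spearman"), 0.5)
})

test_that("holdout compounds never leak into SMOTE parents and metrics are pessimistic", {
  spec <- synthetic_spec(n_compounds = 2500, n_features = 40,
                         n_informative = 8, modulator_fraction = 0.06,
                         seed = 19L)
  lib <- generate_library(spec)
  r <- rank_features(lib$descriptors, lib$log_ros)
  sel <- select_top_k(r, 15)
  ho <- holdout_generalization(lib, sel,
                               dnn_config(hidden_sizes = c(32, 16), epochs = 30),
                               smote_config(), 0.10, seed = 2L)
  expect_equal(length(ho$holdout_ids), round(0.06 * 2500 * 0.1) +
                 round(2500 * (1 - 0.06) * 0.1))
  kept_ids <- setdiff(lib$compound_ids, ho$holdout_ids)
  parent_ids <- kept_ids[ho$provenance$parent_index]
  expect_length(intersect(parent_ids, ho$holdout_ids), 0)
  expect_true(is.finite(ho$metrics$rmse))
})

test_that("model bundles round-trip through save and load", {
  set.seed(14)
  X <- matrix(rnorm(300 * 4), 300, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 2] + rnorm(300, sd = 0.1)
  for (cfg in list(dnn_config(hidden_sizes = c(8), epochs = 5), rf_config())) {
    m <- train_ros_model(X, y, cfg)
    d <- tempfile()
    save_ros_model(m, d)
    m2 <- load_ros_model(d)
    expect_identical(m2$selected_features, m$selected_features)
    expect_equal(predict(m2, X), predict(m, X))
  }
})
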