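#' Regressor configurations
#'
#' `dnn_config()` describes the multilayer-perceptron ROS regressor:
#' three ReLU hidden layers (128/64/32 nodes) plus a linear output
#' layer, Adam-optimised mean-squared-error loss, 100 epochs.
#' `rf_config()` describes the random-forest baseline: 100 trees,
#' unlimited depth.
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param activation,optimizer,loss fixed to `relu`/`adam`/`mse`; kept
#'   as explicit fields so a saved manifest fully describes the model.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed RNG seed (initialisation + shuffling).
#' @export
dnn_config <- function(hidden_sizes = c(128L, 64L, 32L),
                       activation = "relu", optimizer = "adam",
                       epochs = 100L, loss = "mse",
                       batch_size = 32L, learning_rate = 1e-3,
                       seed = 0L) {
  stopifnot(all(hidden_sizes >= 1), epochs >= 1, batch_size >= 1,
            activation == "relu", optimizer == "adam", loss == "mse")
  structure(list(kind = "dnn", hidden_sizes = as.integer(hidden_sizes),
                 activation = activation, optimizer = optimizer,
                 epochs = as.integer(epochs), loss = loss,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = c("dnn_config", "ros_config"))
}

#' @rdname dnn_config
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth, `NULL` = unlimited.
#' @export
rf_config <- function(n_trees = 100L, max_depth = NULL, seed = 0L) {
  stopifnot(n_trees >= 1)
  structure(list(kind = "rf", n_trees = as.integer(n_trees),
                 max_depth = max_depth, seed = as.integer(seed)),
            class = c("rf_config", "ros_config"))
}

#' Random train/test split
#'
#' Reproducible disjoint, exhaustive partition; the test set holds
#' `round(n * test_fraction)` samples.
#'
#' @param X feature matrix; @param y response vector.
#' @param test_fraction fraction in (0,1).
#' @param seed RNG seed.
#' @return list with `train` and `test`, each holding `X`, `y`, `idx`
#'   (row indices into the input).
#' @export
split_train_test <- function(X, y, test_fraction = 0.1, seed = 0L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, test_fraction > 0, test_fraction < 1)
  n_test <- round(n * test_fraction)
  if (n_test == 0 || n_test == n)
    stop("split would leave an empty partition")
  set.seed(seed)
  test_idx <- sort(sample.int(n, n_test))
  train_idx <- setdiff(seq_len(n), test_idx)
  list(train = list(X = X[train_idx, , drop = FALSE], y = y[train_idx],
                    idx = train_idx),
       test = list(X = X[test_idx, , drop = FALSE], y = y[test_idx],
                   idx = test_idx))
}

#' Train a ROS regressor
#'
#' Fits the configured regressor of log10 ROS on descriptors. If
#' `scaler` is supplied, `X` is taken to be already standardised by it
#' (the situation after SMOTE, whose synthetic rows exist only in
#' scaled space); otherwise a scaler is fit on `X` here. The returned
#' model owns its scaler and feature subset, and [predict.ros_model()]
#' expects unscaled descriptors.
#'
#' @param X numeric matrix with feature colnames.
#' @param y log10 ROS response.
#' @param config a [dnn_config()] or [rf_config()].
#' @param scaler optional `feature_scaler` that `X` is already scaled by.
#' @param threshold modulator threshold stored with the model.
#' @return object of class `ros_model`.
#' @export
train_ros_model <- function(X, y, config = dnn_config(), scaler = NULL,
                            threshold = 4.67) {
  stopifnot(inherits(config, "ros_config"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have feature colnames")
  stopifnot(length(y) == nrow(X), all(is.finite(y)))
  if (is.null(scaler)) {
    scaler <- fit_scaler(X)
    Xs <- apply_scaler(scaler, X)
  } else {
    Xs <- X
  }
  fit <- if (config$kind == "dnn") {
    mlp_train_cpp(Xs, y, config$hidden_sizes, config$epochs,
                  config$batch_size, config$learning_rate, config$seed)
  } else {
    ranger::ranger(x = Xs, y = y,
                   num.trees = config$n_trees,
                   max.depth = config$max_depth %||% 0,
                   # ranger treats seed 0 as unseeded; offset keeps 0 valid
                   seed = config$seed + 1L, num.threads = 1)
  }
  structure(list(kind = config$kind, config = config, fit = fit,
                 selected_features = colnames(X), scaler = scaler,
                 threshold = threshold),
            class = "ros_model")
}

#' Predict log10 ROS production
#'
#' @param object a `ros_model`.
#' @param newdata unscaled descriptor matrix whose columns cover the
#'   model's selected features (extra columns are dropped; order is
#'   fixed by name).
#' @param ... unused.
#' @return numeric vector of predicted log10 ROS values.
#' @export
predict.ros_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(object$selected_features))
      stop(sprintf("model expects %d features, got %d unnamed columns",
                   length(object$selected_features), ncol(X)))
    colnames(X) <- object$selected_features
  }
  missing <- setdiff(object$selected_features, colnames(X))
  if (length(missing) > 0)
    stop("missing features: ", paste(missing, collapse = ", "))
  X <- X[, object$selected_features, drop = FALSE]
  Xs <- apply_scaler(object$scaler, X)
  if (object$kind == "dnn") {
    as.vector(mlp_predict_cpp(Xs, object$fit$weights, object$fit$biases))
  } else {
    predict(object$fit, data = Xs, num.threads = 1)$predictions
  }
}

#' @export
print.ros_model <- function(x, ...) {
  cat(sprintf("ros_model (%s): %d features, threshold %.3g\n",
              x$kind, length(x$selected_features), x$threshold))
  invisible(x)
}

#' Regression and threshold-classification metrics
#'
#' RMSE is `sqrt(mean((y - yhat)^2))`. Classification metrics binarise
#' both vectors at the modulator threshold (positive = predicted /
#' actual modulator): precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F-measure = harmonic mean. Ratios with a zero denominator are
#' reported as `NA` and flagged in `$undefined`, never as 0.
#'
#' @param y_true,y_pred numeric vectors of equal length (log10 ROS).
#' @param threshold modulator cutoff.
#' @return object of class `eval_metrics`.
#' @export
evaluate_predictions <- function(y_true, y_pred, threshold = 4.67) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  stopifnot(length(y_true) >= 1)
  rmse <- sqrt(mean((y_true - y_pred)^2))
  pos_true <- y_true >= threshold
  pos_pred <- y_pred >= threshold
  tp <- sum(pos_true & pos_pred)
  fp <- sum(!pos_true & pos_pred)
  fn <- sum(pos_true & !pos_pred)
  tn <- sum(!pos_true & !pos_pred)
  undefined <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision"); NA_real_ }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); NA_real_ }
  f_measure <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else { undefined <- c(undefined, "f_measure"); NA_real_ }
  structure(list(rmse = rmse, precision = precision, recall = recall,
                 f_measure = f_measure, n = length(y_true),
                 tp = tp, fp = fp, fn = fn, tn = tn,
                 threshold = threshold, undefined = undefined),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("n=%d  RMSE=%.4f  precision=%.3f  recall=%.3f  F=%.3f\n",
              x$n, x$rmse, x$precision, x$recall, x$f_measure))
  if (length(x$undefined) > 0)
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Pre-augmentation holdout generalization protocol
#'
#' The default pipeline augments with SMOTE before splitting, which
#' leaks interpolated minority information into the test set and makes
#' its metrics optimistic. This protocol measures generalization to
#' genuinely unseen compounds: a stratified fraction of each class is
#' removed first, SMOTE and training run on the remainder only, and
#' metrics are computed on the untouched holdout.
#'
#' @param library a labelled `compound_library`.
#' @param selected_features feature subset used by the model.
#' @param model_config a [dnn_config()] or [rf_config()].
#' @param smote_cfg a [smote_config()].
#' @param holdout_fraction per-class holdout fraction. Default 0.10.
#' @param seed RNG seed for the stratified draw.
#' @return list with `metrics` ([evaluate_predictions()] on the
#'   holdout), `model`, `holdout_ids`, and the SMOTE `provenance`.
#' @export
holdout_generalization <- function(library, selected_features,
                                   model_config = dnn_config(),
                                   smote_cfg = smote_config(),
                                   holdout_fraction = 0.10, seed = 0L) {
  stopifnot(inherits(library, "compound_library"))
  measured <- which(!is.na(library$log_ros))
  labels <- library$labels[measured]
  X <- library$descriptors[measured, selected_features, drop = FALSE]
  y <- library$log_ros[measured]
  pos <- which(labels); neg <- which(!labels)
  n_pos_h <- round(length(pos) * holdout_fraction)
  n_neg_h <- round(length(neg) * holdout_fraction)
  if (n_pos_h < 1 || n_neg_h < 1 ||
      n_pos_h >= length(pos) || n_neg_h >= length(neg))
    stop("holdout fraction would empty a class")
  set.seed(seed)
  hold <- sort(c(sample(pos, n_pos_h), sample(neg, n_neg_h)))
  keep <- setdiff(seq_along(measured), hold)

  scaler <- fit_scaler(X[keep, , drop = FALSE])
  Xs <- apply_scaler(scaler, X[keep, , drop = FALSE])
  aug <- smote_resample(Xs, labels[keep], smote_cfg, y = y[keep])
  model <- train_ros_model(aug$X_aug, aug$y_aug, model_config,
                           scaler = scaler, threshold = library$threshold)
  model$selected_features <- selected_features
  pred <- predict(model, X[hold, , drop = FALSE])
  list(metrics = evaluate_predictions(y[hold], pred, library$threshold),
       model = model,
       holdout_ids = library$compound_ids[measured][hold],
       provenance = aug$provenance)
}
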