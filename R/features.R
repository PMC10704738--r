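#' Rank descriptors by random-forest importance
#'
#' Fits a random-forest regressor (default 100 trees, unlimited depth)
#' of log10 ROS on the descriptor matrix and returns impurity-decrease
#' importances, normalised to sum to one and sorted descending. The
#' ranking is fit on the un-augmented library: importance estimation
#' precedes SMOTE in the pipeline.
#'
#' @param X numeric matrix (n x F) with feature colnames.
#' @param y numeric response (log10 ROS).
#' @param n_trees number of trees. Default 100.
#' @param seed RNG seed. Default 0 (forest construction only).
#' @param importance `"impurity"` (default) or `"permutation"`.
#' @return object of class `feature_ranking`: `ordered_names`,
#'   `importances` (descending, sum 1), `rf_seed`.
#' @export
rank_features <- function(X, y, n_trees = 100L, seed = 0L,
                          importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 10, length(y) == nrow(X))
  if (any(!is.finite(y))) stop("y must be finite")
  if (sd(y) == 0) stop("constant response: no split gain definable")
  if (is.null(colnames(X))) colnames(X) <- sprintf("feat_%03d", seq_len(ncol(X)))
  fit <- ranger::ranger(
    x = X, y = y,
    num.trees = n_trees,
    importance = importance,
    seed = seed + 1L,  # ranger treats seed 0 as unseeded; offset keeps 0 valid
    num.threads = 1)
  imp <- fit$variable.importance
  imp[imp < 0] <- 0  # permutation importances can dip below zero
  imp <- imp / sum(imp)
  ord <- order(-imp, names(imp))
  structure(list(ordered_names = names(imp)[ord],
                 importances = unname(imp[ord]),
                 rf_seed = seed,
                 n_trees = n_trees,
                 importance_type = importance),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("feature_ranking: %d features, %d trees (%s importance)\n",
              length(x$ordered_names), x$n_trees, x$importance_type))
  cat("top 5:", paste(head(x$ordered_names, 5), collapse = ", "), "\n")
  invisible(x)
}

# elbow of a descending importance curve: locate the point of maximum
# perpendicular distance to the chord joining the first and last points
# (the bend where the change in importance slows down), then keep every
# feature whose importance still exceeds that bend point's
elbow_index <- function(values) {
  n <- length(values)
  if (n < 3) return(n)
  x <- seq_len(n)
  chord <- c(n - 1, values[n] - values[1])
  chord <- chord / sqrt(sum(chord^2))
  dx <- x - 1
  dy <- values - values[1]
  dist <- abs(dx * chord[2] - dy * chord[1])
  bend <- which.max(dist)
  max(sum(values > values[bend]), 1L)
}

#' Select the top-k descriptors from a ranking
#'
#' With `k` given, returns the first `k` names of the ranking (always a
#' prefix; no reordering). Without `k`, applies the chord-distance
#' elbow rule to the sorted importance curve -- the point where the
#' change in importance slows down.
#'
#' @param ranking a [rank_features()] result.
#' @param k optional number of features; `1 <= k <= F`.
#' @return character vector of selected feature names.
#' @export
select_top_k <- function(ranking, k = NULL) {
  stopifnot(inherits(ranking, "feature_ranking"))
  F <- length(ranking$ordered_names)
  if (is.null(k)) {
    k <- elbow_index(ranking$importances)
  } else {
    if (k < 1 || k > F) stop(sprintf("k=%d out of range [1, %d]", k, F))
  }
  ranking$ordered_names[seq_len(k)]
}

#' Write / read a feature ranking
#'
#' The ranking is written as CSV `rank,feature,importance`; a selection
#' is a one-column text file of feature names.
#'
#' @param ranking a `feature_ranking`.
#' @param path output path.
#' @export
write_ranking <- function(ranking, path) {
  write.table(
    data.frame(rank = seq_along(ranking$ordered_names),
               feature = ranking$ordered_names,
               importance = ranking$importances),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @param features character vector of selected names.
#' @export
write_selection <- function(features, path) {
  writeLines(features, path)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_selection <- function(path) readLines(path)
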