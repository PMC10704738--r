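#' Fit a z-score feature scaler
#'
#' Distances drive both SMOTE interpolation and GTM map fitting, so all
#' descriptor matrices are standardised with one scaler fit on the
#' training library. Zero-variance columns keep their mean but get unit
#' standard deviation (they scale to constant 0 and contribute nothing
#' to distances), which keeps column indices stable between the
#' training and screening tables.
#'
#' @param x numeric matrix (n x F), n >= 2.
#' @return object of class `feature_scaler` with `means` and `stddevs`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to fit a scaler")
  means <- colMeans(x)
  stddevs <- apply(x, 2, sd)
  zero <- stddevs == 0 | !is.finite(stddevs)
  if (any(zero)) {
    warning(sprintf("%d zero-variance feature(s) scaled with stddev 1: %s",
                    sum(zero), paste(colnames(x)[zero], collapse = ", ")))
    stddevs[zero] <- 1
  }
  structure(list(means = means, stddevs = stddevs), class = "feature_scaler")
}

#' Apply or invert a fitted scaler
#'
#' @param scaler a `feature_scaler`.
#' @param x numeric matrix with the same column layout the scaler was
#'   fit on.
#' @return the standardised (or de-standardised) matrix.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "feature_scaler"))
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$means))
    stop(sprintf("scaler expects %d columns, got %d", length(scaler$means), ncol(x)))
  sweep(sweep(x, 2, scaler$means, "-"), 2, scaler$stddevs, "/")
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "feature_scaler"))
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$stddevs, "*"), 2, scaler$means, "+")
}
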