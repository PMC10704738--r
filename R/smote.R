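#' SMOTE configuration
#'
#' Hyperparameters of the minority-class oversampler: number of nearest
#' neighbours, random seed, and the sampling strategy (the minority
#' class is oversampled until it matches the majority count).
#'
#' @param k_neighbors neighbours considered per minority point (>= 1).
#' @param seed RNG seed. Default 42.
#' @param strategy only `"minority_to_majority"` is implemented.
#' @export
smote_config <- function(k_neighbors = 5L, seed = 42L,
                         strategy = "minority_to_majority") {
  stopifnot(k_neighbors >= 1)
  strategy <- match.arg(strategy)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed), strategy = strategy),
            class = "smote_config")
}

#' Per-original oversampling quota
#'
#' Ratio of majority to minority counts; each minority original
#' receives `floor(ratio) - 1` synthetic offspring plus possibly one
#' more from randomised assignment of the remainder, so the classes end
#' up exactly balanced.
#'
#' @param minority_n,majority_n class sizes (minority_n >= 1).
#' @return the amplification ratio `majority_n / minority_n`.
#' @export
amplification_factor <- function(minority_n, majority_n) {
  if (minority_n < 1) stop("minority class is empty")
  majority_n / minority_n
}

#' SMOTE oversampling of the minority class
#'
#' Synthetic Minority Over-sampling Technique (Chawla et al. style):
#' each synthetic sample interpolates between a minority point `x` and
#' one of its `k` nearest minority neighbours `z` (Euclidean distance in
#' the -- already standardised -- feature space) as `x + u (z - x)`
#' with `u ~ Uniform(0,1)`. Oversampling continues until the minority
#' count equals the majority count. Original rows are retained unchanged
#' and ordered first; synthetic rows are appended with full provenance.
#'
#' @param X numeric matrix (n x F), standardised features.
#' @param labels logical vector, `TRUE` = minority (modulator) class.
#' @param config a [smote_config()].
#' @param y optional numeric response; synthetic rows receive the same
#'   convex interpolation `y_x + u (y_z - y_x)` as their features.
#' @return list with `X_aug`, `labels_aug`, `y_aug` (when `y` given)
#'   and `provenance` (data frame: synthetic_id, parent_index,
#'   neighbor_index, u -- indices into the rows of `X`).
#' @export
smote_resample <- function(X, labels, config = smote_config(), y = NULL) {
  X <- as.matrix(X)
  labels <- as.logical(labels)
  stopifnot(nrow(X) == length(labels))
  if (!is.null(y)) stopifnot(length(y) == nrow(X))
  n_min <- sum(labels)
  n_maj <- sum(!labels)
  if (n_min == 0 || n_maj == 0) stop("both classes must be present")
  if (n_min > n_maj)
    stop("labelled minority class is larger than the majority class")
  if (n_min <= config$k_neighbors)
    stop(sprintf("minority class (%d) must exceed k_neighbors (%d)",
                 n_min, config$k_neighbors))

  n_syn <- n_maj - n_min
  prov <- data.frame(synthetic_id = character(0), parent_index = integer(0),
                     neighbor_index = integer(0), u = numeric(0),
                     stringsAsFactors = FALSE)
  if (n_syn == 0) {
    return(list(X_aug = X, labels_aug = labels, y_aug = y, provenance = prov))
  }

  min_idx <- which(labels)
  Xm <- X[min_idx, , drop = FALSE]
  # k nearest minority neighbours, ties broken by lower row index
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) {
    order(row, seq_along(row))[seq_len(config$k_neighbors)]
  }))

  set.seed(config$seed)
  base_q <- n_syn %/% n_min
  rem <- n_syn %% n_min
  quota <- rep(base_q, n_min)
  if (rem > 0) {
    extra <- sample.int(n_min, rem)
    quota[extra] <- quota[extra] + 1L
  }

  parents <- rep(seq_len(n_min), times = quota)
  nbr_choice <- sample.int(config$k_neighbors, n_syn, replace = TRUE)
  u <- runif(n_syn)
  neighbors <- nn[cbind(parents, nbr_choice)]

  X_syn <- Xm[parents, , drop = FALSE] +
    u * (Xm[neighbors, , drop = FALSE] - Xm[parents, , drop = FALSE])
  syn_ids <- sprintf("SMOTE%06d", seq_len(n_syn))
  rownames(X_syn) <- syn_ids

  X_aug <- rbind(X, X_syn)
  labels_aug <- c(labels, rep(TRUE, n_syn))
  y_aug <- NULL
  if (!is.null(y)) {
    ym <- y[min_idx]
    y_aug <- c(y, ym[parents] + u * (ym[neighbors] - ym[parents]))
  }
  prov <- data.frame(synthetic_id = syn_ids,
                     parent_index = min_idx[parents],
                     neighbor_index = min_idx[neighbors],
                     u = u, stringsAsFactors = FALSE)
  list(X_aug = X_aug, labels_aug = labels_aug, y_aug = y_aug,
       provenance = prov)
}

#' Write a SMOTE provenance sidecar
#'
#' @param provenance the provenance data frame from [smote_resample()].
#' @param path output CSV path.
#' @export
write_provenance <- function(provenance, path) {
  write.table(provenance, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
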