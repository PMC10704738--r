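# Independent oracles used to cross-check the package implementations.
# These are deliberately naive (loops, exhaustive scans) and share no
# code with the functions they verify.

# small labelled library built directly from matrices
toy_library <- function(n = 30, f = 4, seed = 123, threshold = 4.67) {
  set.seed(seed)
  X <- matrix(rnorm(n * f), n, f,
              dimnames = list(sprintf("c%03d", seq_len(n)),
                              sprintf("d%02d", seq_len(f))))
  ros <- 10^runif(n, 1, 5.7)
  compound_library(X, ros, threshold = threshold)
}

# brute-force k nearest neighbours of row i among rows of X (self excluded,
# ties by lower index)
brute_knn <- function(X, i, k) {
  d <- sqrt(rowSums((X - matrix(X[i, ], nrow(X), ncol(X), byrow = TRUE))^2))
  d[i] <- Inf
  order(d, seq_along(d))[seq_len(k)]
}

# naive responsibility-weighted mean projection: double loop
naive_gtm_project <- function(model, X) {
  Y <- model$basis %*% model$W
  K <- nrow(Y)
  out <- matrix(NA_real_, nrow(X), 2)
  for (n in seq_len(nrow(X))) {
    logp <- numeric(K)
    for (k in seq_len(K)) {
      logp[k] <- -0.5 * model$beta * sum((Y[k, ] - X[n, ])^2)
    }
    w <- exp(logp - max(logp))
    w <- w / sum(w)
    out[n, ] <- c(sum(w * model$latent_points[, 1]),
                  sum(w * model$latent_points[, 2]))
  }
  out
}

# nested-loop interval search over the 8x8 compartment grid
naive_compartment <- function(coords, n_rows = 8, n_cols = 8) {
  xs <- seq(-1, 1, length.out = n_cols + 1)
  ys <- seq(-1, 1, length.out = n_rows + 1)
  out <- integer(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    col <- row <- NA_integer_
    for (c in seq_len(n_cols)) {
      hi_ok <- if (c == n_cols) coords[i, 1] <= xs[c + 1] else coords[i, 1] < xs[c + 1]
      if (coords[i, 1] >= xs[c] && hi_ok) { col <- c - 1; break }
    }
    for (r in seq_len(n_rows)) {
      hi_ok <- if (r == n_rows) coords[i, 2] <= ys[r + 1] else coords[i, 2] < ys[r + 1]
      if (coords[i, 2] >= ys[r] && hi_ok) { row <- r - 1; break }
    }
    out[i] <- as.integer(row * n_cols + col)
  }
  out
}

# exhaustive secondary selection: recompute every rank combination with
# plain loops and pick the per-compartment top-quota by the same rule
naive_secondary <- function(cand, cand_coords, ref_coords, quota,
                            n_rows = 8, n_cols = 8) {
  comp_c <- naive_compartment(cand_coords, n_rows, n_cols)
  comp_r <- naive_compartment(ref_coords, n_rows, n_cols)
  sel <- character(0)
  for (comp in sort(unique(comp_r))) {
    idx <- which(comp_c == comp)
    if (length(idx) == 0) next
    dmin <- numeric(length(idx))
    for (j in seq_along(idx)) {
      dd <- Inf
      for (r in seq_len(nrow(ref_coords))) {
        dd <- min(dd, sqrt(sum((cand_coords[idx[j], ] - ref_coords[r, ])^2)))
      }
      dmin[j] <- dd
    }
    rank_d <- rank(dmin, ties.method = "min")
    rank_p <- rank(-cand$prediction[idx], ties.method = "min")
    score <- rank_d + rank_p
    ord <- order(score, -cand$prediction[idx], cand$compound_id[idx])
    sel <- c(sel, cand$compound_id[idx][ord[seq_len(min(quota, length(idx)))]])
  }
  sort(sel)
}

# chord-distance elbow by exhaustive scan: find the bend (max distance
# to the first-last chord), then count features still above it
naive_elbow <- function(v) {
  n <- length(v)
  x1 <- 1; y1 <- v[1]; x2 <- n; y2 <- v[n]
  bend <- 1; best_d <- -1
  for (i in seq_len(n)) {
    d <- abs((y2 - y1) * i - (x2 - x1) * v[i] + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
    if (d > best_d) { best_d <- d; bend <- i }
  }
  k <- 0
  for (i in seq_len(n)) if (v[i] > v[bend]) k <- k + 1
  max(k, 1)
}
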