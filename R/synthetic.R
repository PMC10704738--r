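#' Specification for a synthetic compound library
#'
#' The generator emulates the statistical shape of an elicitor-triggered
#' ROS screen: a descriptor matrix with correlated continuous and
#' count-like columns, and a log10 luminescence response driven by a
#' planted, partially nonlinear structure-activity relationship (SAR)
#' plus Gaussian noise. The location of the log-ROS distribution is
#' calibrated (a monotone shift) so that exactly
#' `round(n_compounds * modulator_fraction)` compounds sit at or above
#' the modulator threshold -- the generator's hit count is a design
#' condition, not a random outcome.
#'
#' @param n_compounds number of compounds. Default 9991.
#' @param n_features total descriptor count. Default 219.
#' @param n_informative descriptors that drive the response. Default 20.
#' @param modulator_fraction target positive fraction. Default 351/9991.
#' @param ros_range raw luminescence range the response is clipped to.
#'   Default `c(9.5, 540000)`.
#' @param noise_sd response noise, log10 units. Default 0.6.
#' @param correlation_strength share of descriptor variance from shared
#'   latent factors, in \[0,1). Default 0.5.
#' @param threshold modulator threshold, log10 units. Default 4.67.
#' @param location,signal_sd centre and SAR amplitude of the log-ROS
#'   distribution, log10 units (the location is re-shifted by the hit
#'   calibration). Defaults 3.4 and 0.55.
#' @param count_fraction share of non-informative descriptor columns
#'   given count-like (Poisson) marginals. Default 0.3.
#' @param n_latent number of shared latent factors. Default 8.
#' @param seed integer seed; drives all randomness of the generator.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 9991,
                           n_features = 219,
                           n_informative = 20,
                           modulator_fraction = 351 / 9991,
                           ros_range = c(9.5, 540000),
                           noise_sd = 0.6,
                           correlation_strength = 0.5,
                           threshold = 4.67,
                           location = 3.4,
                           signal_sd = 0.55,
                           count_fraction = 0.3,
                           n_latent = 8,
                           seed = 1L) {
  stopifnot(n_informative <= n_features,
            ros_range[1] > 0, ros_range[1] < ros_range[2],
            modulator_fraction > 0, modulator_fraction < 1,
            noise_sd >= 0, correlation_strength >= 0, correlation_strength < 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# truth parameters derived deterministically from spec$seed
derive_truth_params <- function(spec) {
  set.seed(spec$seed)
  F <- spec$n_features
  feature_names <- sprintf("feat_%03d", seq_len(F))
  informative <- sort(sample.int(F, spec$n_informative))
  loadings <- matrix(rnorm(F * spec$n_latent, sd = 1 / sqrt(spec$n_latent)),
                     nrow = F)
  count_pool <- setdiff(seq_len(F), informative)
  n_count <- round(spec$count_fraction * length(count_pool))
  count_cols <- sort(sample(count_pool, n_count))
  count_lambda <- runif(n_count, 2, 30)
  m <- spec$n_informative
  if (m >= 3) {
    i1 <- informative[seq_len(ceiling(m / 3))]
    i2 <- informative[seq(ceiling(m / 3) + 1, ceiling(2 * m / 3))]
    i3 <- informative[seq(ceiling(2 * m / 3) + 1, m)]
  } else {
    i1 <- informative; i2 <- integer(0); i3 <- integer(0)
  }
  # interaction pairs drawn within the middle block
  pairs <- if (length(i2) >= 2) {
    t(replicate(max(1, length(i2) - 1), sample(i2, 2)))
  } else if (length(i2) == 1) {
    matrix(rep(i2, 2), ncol = 2)
  } else matrix(integer(0), ncol = 2)
  list(feature_names = feature_names,
       informative = informative,
       loadings = loadings,
       count_cols = count_cols,
       count_lambda = count_lambda,
       lin_idx = i1, lin_w = rnorm(length(i1)),
       pair_idx = pairs, pair_w = rnorm(nrow(pairs)),
       sat_idx = i3, sat_w = rnorm(length(i3)))
}

# descriptor matrix from the latent-factor model + count marginals
draw_descriptors <- function(tp, spec, n) {
  F <- spec$n_features
  z <- matrix(rnorm(n * spec$n_latent), nrow = n)
  eps <- matrix(rnorm(n * F), nrow = n)
  rho <- spec$correlation_strength
  X <- sqrt(rho) * (z %*% t(tp$loadings)) + sqrt(1 - rho) * eps
  for (j in seq_along(tp$count_cols)) {
    col <- tp$count_cols[j]
    u <- pnorm(X[, col] / sqrt(rho * sum(tp$loadings[col, ]^2) + 1 - rho))
    # keep u strictly inside (0,1) so qpois stays finite
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    X[, col] <- qpois(u, lambda = tp$count_lambda[j])
  }
  colnames(X) <- tp$feature_names
  X
}

# raw (unstandardised) planted SAR signal
raw_signal <- function(tp, X, col_means, col_sds) {
  Xs <- sweep(sweep(X, 2, col_means, "-"), 2, col_sds, "/")
  f <- as.vector(Xs[, tp$lin_idx, drop = FALSE] %*% tp$lin_w)
  for (p in seq_len(nrow(tp$pair_idx))) {
    f <- f + tp$pair_w[p] * Xs[, tp$pair_idx[p, 1]] * Xs[, tp$pair_idx[p, 2]]
  }
  if (length(tp$sat_idx) > 0) {
    f <- f + as.vector(tanh(Xs[, tp$sat_idx, drop = FALSE]) %*% tp$sat_w)
  }
  f
}

#' Generate a synthetic compound library
#'
#' Deterministic given `spec$seed`: two calls with the same spec return
#' bit-identical libraries. The returned library carries its generating
#' ground truth (recoverable with [planted_truth()]).
#'
#' @param spec a [synthetic_spec()].
#' @return a [compound_library()] with a planted-truth attribute.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_compounds
  k <- round(n * spec$modulator_fraction)
  if (k < 1 || k >= n)
    stop(sprintf("infeasible modulator_fraction %.4g for n=%d: %d positives",
                 spec$modulator_fraction, n, k))
  tp <- derive_truth_params(spec)
  set.seed(spec$seed + 1L)
  X <- draw_descriptors(tp, spec, n)
  col_means <- colMeans(X)
  col_sds <- apply(X, 2, sd)
  col_sds[col_sds == 0] <- 1
  f <- raw_signal(tp, X, col_means, col_sds)
  f_mean <- mean(f)
  f_sd <- sd(f)
  noise <- if (spec$noise_sd > 0) rnorm(n, sd = spec$noise_sd) else numeric(n)
  g0 <- spec$location + spec$signal_sd * (f - f_mean) / f_sd + noise
  # shift so the k-th largest value sits exactly on the threshold
  delta <- spec$threshold - sort(g0, decreasing = TRUE)[k]
  lo <- log10(spec$ros_range[1]); hi <- log10(spec$ros_range[2])
  g <- pmin(pmax(g0 + delta, lo), hi)
  # clip again in raw units: 10^log10(x) can undershoot x by an ulp
  ros <- pmin(pmax(10^g, spec$ros_range[1]), spec$ros_range[2])
  rownames(X) <- sprintf("CPD%05d", seq_len(n))
  lib <- compound_library(X, ros_raw = ros, threshold = spec$threshold)
  truth <- structure(
    list(spec = spec, params = tp,
         col_means = col_means, col_sds = col_sds,
         f_mean = f_mean, f_sd = f_sd, delta = delta,
         clip = c(lo, hi)),
    class = "synth_truth")
  attr(lib, "truth") <- truth
  lib
}

#' Recover the planted ground truth of a synthetic library
#'
#' @param library a library produced by [generate_library()] or
#'   [generate_screen_table()].
#' @return list with `informative` (feature names driving the response)
#'   and `f`, a function mapping a descriptor matrix (named columns in
#'   library order) to its noiseless log10 ROS value.
#' @export
planted_truth <- function(library) {
  truth <- attr(library, "truth")
  if (is.null(truth)) stop("library was not produced by the synthetic generator")
  tp <- truth$params
  spec <- truth$spec
  f_fun <- function(X) {
    X <- as.matrix(X)
    if (!is.null(colnames(X))) X <- X[, tp$feature_names, drop = FALSE]
    f <- raw_signal(tp, X, truth$col_means, truth$col_sds)
    g <- spec$location + spec$signal_sd * (f - truth$f_mean) / truth$f_sd + truth$delta
    pmin(pmax(g, truth$clip[1]), truth$clip[2])
  }
  list(informative = tp$feature_names[tp$informative], f = f_fun)
}

#' Generate a screening table from the same planted population
#'
#' Draws fresh compounds from the population of an existing synthetic
#' library: identical SAR, standardisation and hit calibration, new
#' descriptor and noise draws. The true ROS values are attached so that
#' screening enrichment can be scored against ground truth.
#'
#' @param library a synthetic [generate_library()] result.
#' @param n number of screening compounds.
#' @param seed seed for the new draws.
#' @return a `compound_library` sharing the parent's truth attribute.
#' @export
generate_screen_table <- function(library, n, seed) {
  truth <- attr(library, "truth")
  if (is.null(truth)) stop("library was not produced by the synthetic generator")
  spec <- truth$spec
  set.seed(seed)
  X <- draw_descriptors(truth$params, spec, n)
  f <- raw_signal(truth$params, X, truth$col_means, truth$col_sds)
  noise <- if (spec$noise_sd > 0) rnorm(n, sd = spec$noise_sd) else numeric(n)
  g0 <- spec$location + spec$signal_sd * (f - truth$f_mean) / truth$f_sd + noise + truth$delta
  g <- pmin(pmax(g0, truth$clip[1]), truth$clip[2])
  ros <- pmin(pmax(10^g, spec$ros_range[1]), spec$ros_range[2])
  rownames(X) <- sprintf("SCR%07d", seq_len(n))
  lib <- compound_library(X, ros_raw = ros, threshold = spec$threshold)
  attr(lib, "truth") <- truth
  lib
}
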