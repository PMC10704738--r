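#' GTM configuration
#'
#' Generative topographic mapping hyperparameters: a `map_size` grid of
#' latent points on \[-1,1\]^2, an `rbf_grid` of Gaussian basis centres,
#' the basis width, the weight-regularisation constant used in the
#' M-step, and a fixed iteration count (no early stopping).
#'
#' `rbf_sigma` follows the printed convention of the method's users but
#' is ambiguous as an absolute width on a \[-1,1\] map, so the config
#' carries an interpretation switch: `"relative"` (default) multiplies
#' the value by the RBF-centre spacing; `"absolute"` uses it as-is.
#'
#' @param map_size latent grid dimensions. Default `c(15, 15)` (225
#'   latent points).
#' @param rbf_grid basis-centre grid dimensions. Default `c(5, 5)`.
#' @param rbf_sigma basis width parameter. Default 5.
#' @param sigma_mode `"relative"` or `"absolute"`.
#' @param lambda_reg M-step regularisation constant. Default 0.01.
#' @param n_iterations EM iterations. Default 100.
#' @param seed RNG seed (kept for manifest completeness; the fit itself
#'   is deterministic from its PCA initialisation).
#' @export
gtm_config <- function(map_size = c(15L, 15L), rbf_grid = c(5L, 5L),
                       rbf_sigma = 5, sigma_mode = c("relative", "absolute"),
                       lambda_reg = 0.01, n_iterations = 100L, seed = 0L) {
  sigma_mode <- match.arg(sigma_mode)
  stopifnot(all(map_size >= 2), all(rbf_grid >= 2), rbf_sigma > 0,
            lambda_reg >= 0, n_iterations >= 1)
  structure(list(map_size = as.integer(map_size),
                 rbf_grid = as.integer(rbf_grid),
                 rbf_sigma = rbf_sigma, sigma_mode = sigma_mode,
                 lambda_reg = lambda_reg,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "gtm_config")
}

# regular grid of points on [-1,1]^2, row-major from bottom-left
latent_grid <- function(dims) {
  gx <- seq(-1, 1, length.out = dims[1])
  gy <- seq(-1, 1, length.out = dims[2])
  as.matrix(expand.grid(x = gx, y = gy))
}

# K x (M+1) RBF design matrix with bias column
gtm_basis <- function(latent, centers, sigma) {
  d2 <- outer(rowSums(latent^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(latent)), rowSums(centers^2)) -
    2 * latent %*% t(centers)
  cbind(exp(-d2 / (2 * sigma^2)), 1)
}

# responsibilities (K x N) and per-point log evidence for mapped points Y
gtm_estep <- function(Y, X, beta) {
  D <- ncol(X)
  d2 <- outer(rowSums(Y^2), rep(1, nrow(X))) +
    outer(rep(1, nrow(Y)), rowSums(X^2)) - 2 * Y %*% t(X)
  d2[d2 < 0] <- 0
  logp <- -0.5 * beta * d2  # K x N, up to shared constants
  lse <- logsumexp_cols(logp)
  R <- exp(sweep(logp, 2, lse, "-"))
  loglik <- sum(lse) + nrow(X) *
    (0.5 * D * log(beta / (2 * pi)) - log(nrow(Y)))
  list(R = R, loglik = loglik, d2 = d2)
}

#' Fit a generative topographic map
#'
#' Standard GTM expectation-maximisation: latent grid points `z_k` map
#' through an RBF basis `phi` and weight matrix `W` to data space;
#' the E-step computes responsibilities `r_kn` proportional to
#' `exp(-beta/2 ||W' phi(z_k) - x_n||^2)`, the M-step solves the
#' regularised system `(Phi' G Phi + (lambda/beta) I) W = Phi' R X` and
#' updates the noise precision `beta`. Initialisation maps the latent
#' grid onto the first two principal components; `beta^{-1}` starts at
#' the larger of the third PCA eigenvalue and half the mean squared
#' nearest-neighbour distance between mapped points. Runs exactly
#' `n_iterations` and records per iteration both the data
#' log-likelihood and the EM objective (the penalised log-likelihood
#' including the Gaussian weight prior; the two coincide at
#' `lambda_reg = 0`). EM is guaranteed non-decreasing in the latter;
#' with `lambda_reg > 0` the data term can drift marginally once
#' converged.
#'
#' @param X standardised data matrix (N x D), N > M+1, D >= 2.
#' @param config a [gtm_config()].
#' @return object of class `gtm_model`.
#' @export
gtm_fit <- function(X, config = gtm_config()) {
  X <- as.matrix(X)
  N <- nrow(X); D <- ncol(X)
  stopifnot(D >= 2)
  latent <- latent_grid(config$map_size)
  centers <- latent_grid(config$rbf_grid)
  K <- nrow(latent); M <- nrow(centers)
  if (N <= M + 1) stop("need more data points than basis functions")
  spacing <- 2 / (config$rbf_grid[1] - 1)
  sigma <- if (config$sigma_mode == "relative")
    config$rbf_sigma * spacing else config$rbf_sigma
  Phi <- gtm_basis(latent, centers, sigma)

  # PCA initialisation: latent grid spans the first two PCs
  pca <- prcomp(X, center = FALSE, scale. = FALSE)
  ev <- pca$sdev^2
  target <- latent %*% diag(pca$sdev[1:2], 2) %*% t(pca$rotation[, 1:2])
  W <- solve(crossprod(Phi) + 1e-6 * diag(M + 1), crossprod(Phi, target))
  Y <- Phi %*% W
  nn2 <- apply(as.matrix(stats::dist(Y))^2 + diag(Inf, K), 1, min)
  beta_inv <- max(if (length(ev) >= 3) ev[3] else 0, mean(nn2) / 2)
  beta <- 1 / beta_inv

  loglik_trace <- numeric(config$n_iterations)
  objective_trace <- numeric(config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    es <- gtm_estep(Y, X, beta)
    if (any(!is.finite(es$R)))
      stop(sprintf("non-finite responsibilities at iteration %d", it))
    loglik_trace[it] <- es$loglik
    # the EM objective: data log-likelihood plus the Gaussian weight
    # prior implied by the regularised M-step (equal to the data
    # log-likelihood when lambda_reg = 0)
    objective_trace[it] <- es$loglik -
      0.5 * config$lambda_reg * sum(W^2)
    G <- rowSums(es$R)
    A <- crossprod(Phi, Phi * G) + (config$lambda_reg / beta) * diag(M + 1)
    W <- tryCatch(solve(A, crossprod(Phi, es$R %*% X)),
                  error = function(e)
                    stop("singular M-step system despite regularization"))
    Y <- Phi %*% W
    es2 <- gtm_estep(Y, X, beta)  # distances under updated W
    beta <- (N * D) / sum(es$R * es2$d2)
  }

  structure(list(latent_points = latent, rbf_centers = centers,
                 basis = Phi, W = W, beta = beta, sigma = sigma,
                 config = config, data_dim = D,
                 loglik_trace = loglik_trace,
                 objective_trace = objective_trace),
            class = "gtm_model")
}

#' @export
print.gtm_model <- function(x, ...) {
  cat(sprintf("gtm_model: %d latent points, %d RBFs, D=%d, beta=%.4g\n",
              nrow(x$latent_points), nrow(x$rbf_centers), x$data_dim, x$beta))
  invisible(x)
}

#' GTM responsibilities for new data
#'
#' Posterior probability that each latent grid point generated each
#' data point; columns sum to one.
#'
#' @param model a `gtm_model`.
#' @param X data matrix in the scaling of the fit.
#' @return K x N responsibility matrix.
#' @export
gtm_responsibilities <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$data_dim)
    stop(sprintf("model expects %d columns, got %d", model$data_dim, ncol(X)))
  gtm_estep(model$basis %*% model$W, X, model$beta)$R
}

#' Project data onto the 2-D GTM map
#'
#' Posterior-mean projection: each point maps to its responsibility-
#' weighted average of the latent grid, hence always inside \[-1,1\]^2
#' (the convex hull of the grid). `mode = "mode"` returns the latent
#' point with the highest responsibility instead.
#'
#' @param model a `gtm_model`.
#' @param X data matrix, same columns and scaling as the fit.
#' @param mode `"mean"` (default) or `"mode"`.
#' @return N x 2 matrix of map coordinates.
#' @export
gtm_project <- function(model, X, mode = c("mean", "mode")) {
  mode <- match.arg(mode)
  R <- gtm_responsibilities(model, X)
  if (mode == "mean") {
    coords <- t(R) %*% model$latent_points
  } else {
    coords <- model$latent_points[apply(R, 2, which.max), , drop = FALSE]
  }
  dimnames(coords) <- list(rownames(as.matrix(X)), c("x", "y"))
  coords
}
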