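fit_small_gtm <- function(n = 300, d = 5, seed = 1,
                          config = gtm_config(n_iterations = 30)) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * d), n, d))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  list(X = X, model = gtm_fit(X, config))
}

test_that("default configuration yields 225 latent points and 25 basis functions", {
  f <- fit_small_gtm()
  expect_equal(nrow(f$model$latent_points), 225)
  expect_equal(nrow(f$model$rbf_centers), 25)
  expect_equal(dim(f$model$basis), c(225, 26))
  expect_gt(f$model$beta, 0)
})

test_that("responsibilities are a proper posterior over the latent grid", {
  f <- fit_small_gtm(seed = 2)
  R <- gtm_responsibilities(f$model, f$X)
  expect_equal(unname(colSums(R)), rep(1, nrow(f$X)), tolerance = 1e-9)
  expect_true(all(R >= 0))
})

test_that("the EM objective is non-decreasing over iterations", {
  for (s in 1:3) {
    f <- fit_small_gtm(n = 250, d = 6, seed = s,
                       config = gtm_config(n_iterations = 40))
    expect_true(all(diff(f$model$objective_trace) >= -1e-8))
    # the data term tracks it closely and improves overall
    expect_gt(f$model$loglik_trace[40], f$model$loglik_trace[1])
  }
})

test_that("posterior-mean projections stay inside the map and match a naive oracle", {
  f <- fit_small_gtm(n = 150, d = 3, seed = 3)
  co <- gtm_project(f$model, f$X)
  expect_true(all(co >= -1 & co <= 1))
  expect_equal(unname(co[1:50, ]), naive_gtm_project(f$model, f$X[1:50, ]),
               tolerance = 1e-9)
})

test_that("a degenerate map with uniform responsibilities projects to the grid centroid", {
  f <- fit_small_gtm(n = 100, d = 4)
  m <- f$model
  m$W <- matrix(0, nrow(m$W), ncol(m$W))  # every latent point maps to the origin
  R <- gtm_responsibilities(m, f$X[1:5, , drop = FALSE])
  expect_equal(unname(R), matrix(1 / 225, 225, 5), tolerance = 1e-12)
  co <- gtm_project(m, f$X[1:5, , drop = FALSE])
  expect_equal(unname(co), matrix(0, 5, 2), tolerance = 1e-12)
})

test_that("fitting is deterministic and projection is permutation-equivariant", {
  f1 <- fit_small_gtm(n = 120, d = 4, seed = 5)
  f2 <- fit_small_gtm(n = 120, d = 4, seed = 5)
  expect_identical(f1$model$W, f2$model$W)
  expect_identical(f1$model$loglik_trace, f2$model$loglik_trace)
  co <- gtm_project(f1$model, f1$X)
  perm <- sample(nrow(f1$X))
  expect_equal(unname(gtm_project(f1$model, f1$X[perm, ])), unname(co[perm, ]))
})

test_that("a low-dimensional manifold's dominant coordinate is recovered", {
  set.seed(2)
  a <- runif(500, -2, 2); b <- runif(500, -0.5, 0.5)
  X <- cbind(a, b, 0.4 * a^2) + matrix(rnorm(1500, sd = 0.02), 500, 3)
  Xc <- scale(X, scale = FALSE)
  m <- gtm_fit(Xc, gtm_config())
  co <- gtm_project(m, Xc)
  best <- max(abs(cor(co[, 1], a, method = "spearman")),
              abs(cor(co[, 2], a, method = "spearman")))
  expect_gt(best, 0.9)
})

test_that("posterior-mode projection lands on latent grid points", {
  f <- fit_small_gtm(n = 100, d = 3, seed = 7)
  co <- gtm_project(f$model, f$X, mode = "mode")
  grid_keys <- paste(f$model$latent_points[, 1], f$model$latent_points[, 2])
  expect_true(all(paste(co[, 1], co[, 2]) %in% grid_keys))
})

test_that("dimension mismatches and tiny data sets are rejected", {
  f <- fit_small_gtm(n = 60, d = 3)
  expect_error(gtm_responsibilities(f$model, matrix(0, 5, 4)), "expects 3")
  expect_error(gtm_fit(matrix(rnorm(40), 20, 2), gtm_config()), "more data")
})

test_that("absolute and relative RBF width conventions both give usable fits", {
  f_rel <- fit_small_gtm(n = 200, d = 4, seed = 9,
                         config = gtm_config(n_iterations = 20))
  f_abs <- fit_small_gtm(n = 200, d = 4, seed = 9,
                         config = gtm_config(n_iterations = 20,
                                             sigma_mode = "absolute"))
  for (f in list(f_rel, f_abs)) {
    co <- gtm_project(f$model, f$X)
    expect_true(all(is.finite(co)))
    expect_true(all(co >= -1 & co <= 1))
    # regularisation penalises W, so only overall improvement of the
    # data term is guaranteed across sigma conventions
    tr <- f$model$loglik_trace
    expect_gt(tr[length(tr)], tr[1])
  }
})
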