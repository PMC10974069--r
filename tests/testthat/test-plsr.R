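test_that("single-predictor PLSR reproduces simple least squares", {
  set.seed(1)
  x <- rnorm(20)
  y <- 2 + 3 * x + rnorm(20, 0, 0.2)
  m <- fit_plsr(matrix(x, ncol = 1), y, 1)
  ls <- stats::coef(stats::lm(y ~ x))
  expect_equal(m$regression_vector, unname(ls[2]), tolerance = 1e-10)
  expect_equal(m$intercept, unname(ls[1]), tolerance = 1e-10)
})

test_that("full-component PLSR on full-rank tall X equals OLS", {
  set.seed(2)
  X <- matrix(rnorm(30 * 5), 30)
  y <- drop(X %*% c(1, -2, 0.5, 3, -1)) + rnorm(30, 0, 0.1)
  m <- fit_plsr(X, y, 5)
  ols <- drop(cbind(1, X) %*% stats::coef(stats::lm(y ~ X)))
  expect_equal(predict(m, X), ols, tolerance = 1e-8)
})

test_that("a planted single-channel signal is captured by one component", {
  # n large enough that spurious correlations of the 9 noise channels
  # (~ 1/sqrt(n) each) cost less than 1% of the variance at one component
  set.seed(3)
  X <- matrix(rnorm(2000 * 10), 2000)
  y <- 1.5 * X[, 4] + rnorm(2000, 0, 1e-6)
  m <- fit_plsr(X, y, 1)
  expect_gte(r2(y, predict(m, X)), 0.99)
})

test_that("model identities and structural invariants hold", {
  set.seed(4)
  X <- matrix(rnorm(15 * 8), 15)
  y <- drop(X %*% rnorm(8)) + rnorm(15, 0, 0.2)
  m <- fit_plsr(X, y, 5)
  # centering identity and duplicate-row consistency
  expect_equal(unname(predict(m, colMeans(X))), mean(y), tolerance = 1e-10)
  expect_equal(predict(m, X[c(3, 3), ]), rep(predict(m, X[3, ]), 2),
               ignore_attr = TRUE)
  # mutual orthogonality of NIPALS scores
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  # two-route prediction: regression vector vs explicit score-space walk
  Xc <- sweep(sweep(X, 2, m$x_mean), 2, m$x_sd, "/")
  yhat <- rep(0, nrow(X))
  for (k in seq_len(m$ncomp)) {
    t_k <- Xc %*% m$weights[, k]
    yhat <- yhat + m$y_loadings[k] * drop(t_k)
    Xc <- Xc - t_k %*% t(m$x_loadings[, k])
  }
  expect_equal(m$y_mean + m$y_sd * yhat, predict(m, X), tolerance = 1e-8)
  # deflation exactness at full rank
  mf <- fit_plsr(X, y, 8)
  Xc0 <- sweep(sweep(X, 2, mf$x_mean), 2, mf$x_sd, "/")
  resid <- Xc0 - mf$scores %*% t(mf$x_loadings)
  expect_lt(norm(resid, "F") / norm(Xc0, "F"), 1e-6)
  # channel reordering invariance
  perm <- sample(8)
  mp <- fit_plsr(X[, perm], y, 5)
  expect_equal(predict(mp, X[, perm]), predict(m, X), tolerance = 1e-8)
})

test_that("degenerate inputs are rejected and zero-variance channels dropped", {
  set.seed(5)
  X <- matrix(rnorm(12 * 4), 12)
  y <- rnorm(12)
  expect_error(fit_plsr(X, rep(1, 12), 2), "constant")
  expect_error(fit_plsr(X, y, 12), "ncomp")
  Xz <- cbind(X, 7)
  expect_warning(m <- fit_plsr(Xz, y, 2), "zero-variance")
  expect_identical(m$regression_vector[5], 0)
  expect_error(predict(m, X), "channel count")
})

test_that("cross_validate matches brute-force leave-one-out refits", {
  set.seed(6)
  X <- matrix(rnorm(5 * 3), 5)
  y <- drop(X %*% c(1, 2, -1)) + rnorm(5, 0, 0.3)
  cv <- cross_validate(X, y, max_ncomp = 1)
  expect_equal(cv$rmse_cv_by_ncomp[1], loo_cv_bruteforce(X, y, 1),
               tolerance = 1e-10)
  # larger case, all component counts
  set.seed(7)
  X2 <- matrix(rnorm(12 * 6), 12)
  y2 <- drop(X2 %*% rnorm(6)) + rnorm(12, 0, 0.4)
  cv2 <- cross_validate(X2, y2, max_ncomp = 4)
  for (k in 1:4)
    expect_equal(cv2$rmse_cv_by_ncomp[k], loo_cv_bruteforce(X2, y2, k),
                 tolerance = 1e-10)
  expect_identical(cv2$chosen_ncomp,
                   as.integer(which.min(cv2$rmse_cv_by_ncomp)))
})

test_that("cross_validate behaviour on structured data", {
  # pure noise around a constant: RMSEcv ~ noise scale for every ncomp
  set.seed(8)
  X <- matrix(rnorm(20 * 10), 20)
  y <- 5 + rnorm(20, 0, 0.01)
  cv <- cross_validate(X, y, max_ncomp = 3)
  expect_true(all(cv$rmse_cv_by_ncomp < 0.05))
  # one planted latent factor: X is exactly rank 1, so the first component
  # exhausts it and later components tie (first minimum wins)
  set.seed(9)
  t1 <- rnorm(25)
  X1 <- t1 %*% t(rnorm(12))
  y1 <- t1 + rnorm(25, 0, 0.05)
  cv1 <- cross_validate(X1, y1, max_ncomp = 5)
  expect_identical(cv1$chosen_ncomp, 1L)
  # LOO pooled RMSE invariant to sample ordering
  perm <- sample(25)
  cv1p <- cross_validate(X1[perm, ], y1[perm], max_ncomp = 5)
  expect_equal(cv1p$rmse_cv_by_ncomp, cv1$rmse_cv_by_ncomp, tolerance = 1e-10)
  # infeasible component budget
  expect_error(cross_validate(X1, y1, max_ncomp = 25), "infeasible")
})

test_that("NIPALS agrees with the scikit-learn PLSR oracle", {
  # small spot-check here; the full 25-instance sweep runs in acceptance
  set.seed(10)
  cases <- lapply(1:3, function(i) {
    X <- matrix(rnorm(20 * 50), 20)
    y <- drop(X[, 1:5] %*% rnorm(5)) + rnorm(20, 0, 0.5)
    list(X = X, y = y, Xnew = matrix(rnorm(8 * 50), 8), ncomp = 4)
  })
  oracle <- sklearn_pls_predict(cases)
  for (i in seq_along(cases)) {
    m <- fit_plsr(cases[[i]]$X, cases[[i]]$y, cases[[i]]$ncomp)
    ours <- predict(m, cases[[i]]$Xnew)
    expect_lt(max(abs(ours - oracle[[i]])) / max(abs(oracle[[i]])), 1e-6)
  }
})

test_that("models serialize to JSON and back", {
  set.seed(11)
  X <- matrix(rnorm(15 * 6), 15)
  y <- drop(X %*% rnorm(6)) + rnorm(15, 0, 0.1)
  m <- fit_plsr(X, y, 3)
  f <- tempfile(fileext = ".json")
  plsr_to_json(m, f)
  back <- plsr_from_json(f)
  expect_equal(predict(back, X), predict(m, X), tolerance = 1e-12)
  expect_identical(back$ncomp, m$ncomp)
  unlink(f)
})

test_that("k-fold folds partition samples and are seed-stable", {
  f <- cv_folds(10, "kfold", k = 3, seed = 1)
  expect_identical(sort(unique(f)), 1:3)
  expect_length(f, 10)
  expect_identical(f, cv_folds(10, "kfold", k = 3, seed = 1))
  expect_identical(cv_folds(4, "loo"), 1:4)
})
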