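test_that("OLS matches the normal-equations oracle", {
  set.seed(41)
  X <- cbind(1, matrix(rnorm(600), 200, 3))
  colnames(X) <- c("(Intercept)", "x1", "x2", "x3")
  y <- rnorm(200)
  f <- fit_ols(X, y)
  b_oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(f$coefficients), as.numeric(b_oracle),
               tolerance = 1e-10)
  s2 <- sum((y - X %*% b_oracle)^2) / (200 - 4)
  expect_equal(unname(f$vcov), s2 * solve(t(X) %*% X), tolerance = 1e-10,
               ignore_attr = TRUE)
  # exact linear response: zero residual variance, exact coefficients
  yx <- as.numeric(X %*% c(1, 2, -1, 0.5))
  fx <- fit_ols(X, yx)
  expect_equal(unname(fx$coefficients), c(1, 2, -1, 0.5), tolerance = 1e-10)
  expect_lt(fx$sigma2_e, 1e-20)
  # intercept-only model gives the sample mean
  f0 <- fit_ols(matrix(1, 200, 1, dimnames = list(NULL, "(Intercept)")), y)
  expect_equal(unname(f0$coefficients), mean(y))
  # rank deficiency is reported with the collinear column
  Xr <- cbind(X, dup = X[, "x1"])
  expect_error(fit_ols(Xr, y), "collinear.*dup|dup")
})

test_that("GLS with identity relationship reproduces OLS", {
  set.seed(42)
  n <- 120
  X <- cbind("(Intercept)" = 1, a = rnorm(n), b = rbinom(n, 1, 0.4))
  y <- X %*% c(0.5, 1, -0.3) + rnorm(n)
  K <- diag(n); dimnames(K) <- list(sprintf("S%d", 1:n), sprintf("S%d", 1:n))
  ols <- fit_ols(X, y)
  lmm <- fit_lmm_reml(X, y, K)
  expect_equal(lmm$coefficients, ols$coefficients, tolerance = 1e-8)
  # with V proportional to I the coefficient covariance is the OLS one,
  # however the flat likelihood splits the total variance
  expect_equal(lmm$vcov, ols$vcov, tolerance = 1e-6)
})

test_that("REML optimum beats random lambda probes and is scale invariant", {
  p <- generative_params(sigma_g = 0.5)
  ds <- simulate_dataset(p, 300, seed = 43, family_size = 5)
  X <- cbind("(Intercept)" = 1, A = ds$A[, 1], ds$C)
  f <- fit_lmm_reml(X, ds$Y, ds$kinship)
  # recompute the profiled criterion at random lambda values
  K <- 2 * ds$kinship$phi
  ev <- eigen(K, symmetric = TRUE)
  yt <- crossprod(ev$vectors, ds$Y)
  Xt <- crossprod(ev$vectors, X)
  n <- nrow(X); pp <- ncol(X)
  crit <- function(lam) {
    w <- 1 / (pmax(ev$values, 0) * lam + 1)
    XtWX <- crossprod(Xt, Xt * w)
    beta <- solve(XtWX, crossprod(Xt, yt * w))
    s2 <- sum(w * (yt - Xt %*% beta)^2) / (n - pp)
    -0.5 * ((n - pp) * log(s2) + sum(log(lam * pmax(ev$values, 0) + 1)) +
              determinant(XtWX)$modulus[1] + (n - pp))
  }
  set.seed(44)
  probes <- exp(runif(25, log(1e-6), log(1e6)))
  expect_true(all(f$logreml >= vapply(probes, crit, numeric(1)) - 1e-6))
  # multiplying the relationship matrix by a positive scalar leaves the
  # coefficients unchanged (absorbed into the variance components)
  f2 <- fit_lmm_reml(X, ds$Y, 7.3 * K)
  expect_equal(f2$coefficients, f$coefficients, tolerance = 1e-6)
  expect_error(fit_lmm_reml(X, ds$Y, -K), "positive semi-definite")
})

test_that("variance components are recovered in sibship simulations", {
  # null polygenic signal: sigma_g^2 estimates collapse to ~0 mostly
  p0 <- generative_params(sigma_g = 0)
  lam0 <- vapply(1:20, function(r) {
    ds <- simulate_dataset(p0, 200, seed = 500 + r, family_size = 5)
    X <- cbind("(Intercept)" = 1, A = ds$A[, 1], ds$C)
    f <- fit_lmm_reml(X, ds$Y, ds$kinship)
    f$sigma2_g / f$sigma2_e
  }, numeric(1))
  expect_gte(mean(lam0 < 0.25), 0.9)

  # sigma_g^2 / sigma_e^2 = 1: median ratio estimate within a factor of 2
  p1 <- generative_params(sigma_g = 0.4, sigma_y = 0.4)
  lam1 <- vapply(1:20, function(r) {
    ds <- simulate_dataset(p1, 300, seed = 700 + r, family_size = 10)
    X <- cbind("(Intercept)" = 1, A = ds$A[, 1], ds$C)
    f <- fit_lmm_reml(X, ds$Y, ds$kinship)
    f$sigma2_g / f$sigma2_e
  }, numeric(1))
  expect_true(median(lam1) >= 0.5 && median(lam1) <= 2.0)
})
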