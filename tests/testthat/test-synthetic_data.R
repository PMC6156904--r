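test_that("genotype simulator respects Hardy-Weinberg frequencies", {
  d <- simulate_genotypes(100000, maf = 0.359, seed = 11)
  expect_true(abs(mean(d) - 2 * 0.359) < 0.006)
  expect_identical(simulate_genotypes(500, 0.2, seed = 3),
                   simulate_genotypes(500, 0.2, seed = 3))
  expect_error(simulate_genotypes(10, 0.7), "maf")
  expect_error(simulate_genotypes(10, 0), "maf")
  # rare-allele limit: dosages almost surely 0
  expect_true(mean(simulate_genotypes(1000, 1e-6, seed = 4)) < 1e-3)
})

test_that("simulated datasets follow the generative regression structure", {
  # near-deterministic mediator: M is the affine map beta0 + beta1 * A
  p <- generative_params(beta0 = 0.1, beta1 = 0.3, beta2 = 0,
                         sigma_m = 1e-12)
  ds <- simulate_dataset(p, 200, seed = 5)
  expect_equal(unname(ds$M[, 1]), unname(0.1 + 0.3 * ds$A[, 1]),
               tolerance = 1e-9)

  # OLS of M on A is consistent for beta1
  p2 <- generative_params(beta1 = 0.5, sigma_m = 1)
  ds2 <- simulate_dataset(p2, 200000, seed = 6)
  slope <- coef(lm(ds2$M[, 1] ~ ds2$A[, 1]))[2]
  expect_true(abs(slope - 0.5) < 0.01)

  # complete null: Y unrelated to A
  p0 <- generative_params(beta1 = 0, theta1 = 0, theta2 = 0, theta3 = 0)
  ds0 <- simulate_dataset(p0, 50000, seed = 7)
  sm <- summary(lm(ds0$Y ~ ds0$A[, 1]))$coefficients
  expect_true(abs(sm[2, 1]) < 3 * sm[2, 2])

  # reproducibility: identical seed, identical dataset
  expect_identical(simulate_dataset(p2, 100, seed = 9),
                   simulate_dataset(p2, 100, seed = 9))
  expect_error(simulate_dataset(p2, 10, seed = 1, family_size = 3),
               "family_size")
  expect_error(generative_params(sigma_m = -1), "sigma_m")
})

test_that("counterfactual oracle matches the product closed form", {
  set.seed(21)
  for (i in 1:5) {
    p <- generative_params(
      beta1 = runif(1, -0.5, 0.5), beta2 = runif(1, -0.2, 0.2),
      theta2 = runif(1, -2, 2), theta3 = runif(1, -1, 1),
      sigma_m = runif(1, 0.02, 0.3))
    o <- oracle_nie_monte_carlo(p, n_draws = 20000, seed = 100 + i)
    expect_true(abs(o$nie - p$beta1 * (p$theta2 + p$theta3)) < 3 * o$mc_se)
  }
  # structural zeros
  o0 <- oracle_nie_monte_carlo(generative_params(beta1 = 0), n_draws = 20000,
                               seed = 1)
  expect_true(abs(o0$nie) < 3 * o0$mc_se + 1e-12)
  oc <- oracle_nie_monte_carlo(generative_params(theta2 = -0.7, theta3 = 0.7,
                                                 beta1 = 0.3),
                               n_draws = 20000, seed = 2)
  expect_true(abs(oc$nie) < 3 * oc$mc_se + 1e-12)
})

test_that("sibling outcome covariance grows with the polygenic SD", {
  sib_cov <- function(sigma_g, seed) {
    p <- generative_params(beta1 = 0, theta2 = 0, theta3 = 0,
                           sigma_g = sigma_g)
    ds <- simulate_dataset(p, 2000, seed = seed, family_size = 2)
    y <- matrix(ds$Y, nrow = 2)  # columns = sib pairs
    cov(y[1, ], y[2, ])
  }
  cc <- vapply(c(0.2, 0.5, 1.0), sib_cov, numeric(1), seed = 31)
  expect_true(all(diff(cc) > 0))
  expect_gt(cc[3], 0)
})

test_that("study writer emits files the readers accept, consistently", {
  d <- withr::local_tempdir()
  paths <- write_study(d, generative_params(beta1 = 0.05, theta1 = 0.2),
                       n = 120, n_snps = 5, n_cpgs = 5, seed = 13,
                       p_missing_post = 0.2)
  g <- read_genotypes(paths$vcf)
  mp <- read_methylation(paths$meth_pre, paths$meth_post,
                         paths$cpg_positions)
  pt <- read_phenotypes(paths$phenotypes)
  expect_equal(ncol(g$dosages), 5)
  screening <- align_complete_cases(g, mp, pt, require_mediator = FALSE)
  mediation <- align_complete_cases(g, mp, pt, require_mediator = TRUE)
  expect_equal(length(screening$sample_ids), 120)
  expect_equal(length(mediation$sample_ids), 120 - 24)
})
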