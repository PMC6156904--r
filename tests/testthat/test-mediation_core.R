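test_that("NIE point estimate and delta SE match hand-expanded formulas", {
  med <- manual_fit(c("(Intercept)" = 0, A = 0.5),
                    diag(c(0, 0.01)))
  vc_out <- diag(c(0, 0, 0.04, 0.04))
  vc_out[3, 4] <- vc_out[4, 3] <- -0.01
  out <- manual_fit(c("(Intercept)" = 0, A = 0, M = 1.0, "A:M" = 0.2),
                    vc_out)
  r <- estimate_nie(med, out)
  expect_equal(r$nie, 0.5 * (1.0 + 0.2))
  # G S G' = (th2+th3)^2 var(b1) + b1^2 (var th2 + var th3 + 2 cov)
  expect_equal(r$se, sqrt(1.44 * 0.01 + 0.25 * (0.04 + 0.04 - 0.02)),
               tolerance = 1e-12)
  expect_equal(r$se, sqrt(0.0294), tolerance = 1e-12)
  expect_equal(r$p, 2 * pnorm(-abs(r$nie / r$se)))

  # beta1 = 0 exactly: NIE 0 but its SE stays positive
  med0 <- manual_fit(c("(Intercept)" = 0, A = 0), diag(c(0, 0.01)))
  r0 <- estimate_nie(med0, out)
  expect_identical(r0$nie, 0)
  expect_equal(r0$se, sqrt(1.44 * 0.01))
  # theta2 + theta3 = 0: NIE exactly 0
  outz <- manual_fit(c("(Intercept)" = 0, A = 0, M = 0.7, "A:M" = -0.7),
                     vc_out)
  expect_identical(estimate_nie(med, outz)$nie, 0)
  # mismatched covariate sets are rejected
  med2 <- manual_fit(c("(Intercept)" = 0, A = 0.5, age = 1), diag(3) * 0.01)
  expect_error(estimate_nie(med2, out), "covariate")
})

test_that("joint model fits recover the generative parameters", {
  p <- generative_params(beta1 = 0.02, theta1 = 0.1, theta2 = -1.661,
                         theta3 = 0.713, sigma_m = 0.05)
  ds <- simulate_dataset(p, 5000, seed = 61)
  med <- fit_mediator_model(ds, "snp1", "cg1")
  out <- fit_outcome_model(ds, "snp1", "cg1")
  expect_true(abs(med$coefficients["A"] - 0.02) <
                3 * sqrt(med$vcov["A", "A"]))
  expect_true(abs(out$coefficients["M"] + 1.661) <
                3 * sqrt(out$vcov["M", "M"]))
  expect_true(abs(out$coefficients["A:M"] - 0.713) <
                3 * sqrt(out$vcov["A:M", "A:M"]))
  # NIE via fits agrees with plugging the estimates into the product
  r <- estimate_nie(med, out)
  expect_equal(r$nie, unname(med$coefficients["A"] *
                               (out$coefficients["M"] +
                                  out$coefficients["A:M"])))
  # degenerate inputs
  ds$M[, 1] <- 0.25
  expect_error(fit_mediator_model(ds, "snp1", "cg1"), "constant")
  ds2 <- simulate_dataset(p, 500, seed = 62)
  ds2$A[, 1] <- 1
  expect_error(fit_outcome_model(ds2, "snp1", "cg1"), "collinear")
})

test_that("delta-method SE agrees with a nonparametric bootstrap", {
  p <- generative_params(beta1 = 0.02, theta2 = -1, theta3 = 0.5,
                         sigma_m = 0.05, sigma_y = 0.4)
  ds <- simulate_dataset(p, 2000, seed = 63)
  med <- fit_mediator_model(ds, "snp1", "cg1")
  out <- fit_outcome_model(ds, "snp1", "cg1")
  delta_se <- estimate_nie(med, out)$se
  set.seed(64)
  boot <- replicate(500, {
    idx <- sample.int(2000, replace = TRUE)
    Xm <- cbind(1, A = ds$A[idx, 1], ds$C[idx, ])
    Xo <- cbind(1, A = ds$A[idx, 1], M = ds$M[idx, 1],
                ds$A[idx, 1] * ds$M[idx, 1], ds$C[idx, ])
    b1 <- qr.coef(qr(Xm), ds$M[idx, 1])[2]
    th <- qr.coef(qr(Xo), ds$Y[idx])[3:4]
    b1 * sum(th)
  })
  expect_true(sd(boot) / delta_se > 0.85 && sd(boot) / delta_se < 1.15)
})

test_that("interaction Wald test maps estimates to normal p-values", {
  out <- manual_fit(c("(Intercept)" = 0, A = 0, M = 0, "A:M" = 0),
                    diag(4))
  expect_equal(test_interaction(out)$p, 1)
  out2 <- manual_fit(c("(Intercept)" = 0, A = 0, M = 0, "A:M" = 1.96),
                     diag(4))
  expect_equal(test_interaction(out2)$p, 0.05, tolerance = 1e-3)
})

test_that("genotype-stratified slopes recover theta2 + theta3 * a", {
  p <- generative_params(maf = 0.45, beta1 = 0, theta2 = 0, theta3 = 1,
                         sigma_m = 0.1)
  ds <- simulate_dataset(p, 10000, seed = 65)
  st <- stratified_methylation_effects(ds, "snp1", "cg1")
  expect_equal(st$genotype, 0:2)
  for (a in 0:2) {
    row <- st[st$genotype == a, ]
    expect_true(abs(row$beta - a) < 3 * row$se)
  }
  expect_equal(sum(st$n), 10000)
  # a tiny stratum is reported absent
  ds$A[ds$A[, 1] == 2, 1] <- 1
  expect_warning(st2 <- stratified_methylation_effects(ds, "snp1", "cg1"),
                 "stratum 2")
  expect_equal(st2$genotype, 0:1)
})

test_that("Bonferroni threshold is alpha over the number of tests", {
  expect_equal(signif(bonferroni_threshold(0.05, 322), 3), 0.000155)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("the per-pair report composes the individual estimators", {
  p <- generative_params(beta1 = 0.05, theta1 = 0.2, sigma_m = 0.05)
  ds <- simulate_dataset(p, 800, seed = 66)
  pairs <- data.frame(snp = "snp1", cpg = "cg1")
  rep1 <- mediation_report(ds, pairs)
  te <- fit_total_effect(ds, "snp1")
  med <- fit_mediator_model(ds, "snp1", "cg1")
  out <- fit_outcome_model(ds, "snp1", "cg1")
  nie <- estimate_nie(med, out)
  expect_equal(rep1$te, te$estimate)
  expect_equal(rep1$nde, unname(out$coefficients["A"]))
  expect_equal(rep1$nie, nie$nie)
  expect_equal(rep1$nie_p, nie$p)
  expect_equal(rep1$int_p, test_interaction(out)$p)
  expect_equal(rep1$distance_kb, 12.5)
  expect_equal(rep1$maf, unname(ds$variants$maf[1]))
})
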