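# Joint mediator/outcome model fitting at selected SNP-CpG pairs, the
# natural indirect effect (NIE) with its delta-method standard error, the
# gene-methylation interaction test, genotype-stratified methylation
# effects, and report assembly.

#' Fit the mediator model at a SNP-CpG pair
#'
#' `E(M | A, C) = beta0 + beta1 * A + beta2' C`, where M is the change in
#' methylation beta value at the CpG site and A the alternate-allele dosage.
#'
#' @param dataset an `analysis_dataset` complete for genotype, mediator,
#'   outcome and covariates (the mediation sample).
#' @param snp variant id (column of `dataset$A`).
#' @param cpg CpG id (column of `dataset$M`).
#' @param mode fitting mode: `"auto"` (LMM when kinship is attached), `"ols"`
#'   or `"lmm"`.
#' @return A `model_fit` with coefficients `(Intercept)`, `A`, then the
#'   covariate columns.
#' @export
fit_mediator_model <- function(dataset, snp, cpg, mode = "auto") {
  M <- dataset$M[, cpg]
  if (anyNA(M)) stop("mediator has missing values; use the mediation sample")
  if (stats::var(M) == 0)
    stop("methylation change at ", cpg, " is constant (degenerate mediator)")
  A <- dataset$A[, snp]
  X <- cbind("(Intercept)" = 1, A = A, dataset$C)
  fit_model(X, M, dataset$kinship, mode)
}

#' Fit the outcome model with exposure-mediator interaction
#'
#' `E(Y | A, M, C) = theta0 + theta1 * A + theta2 * M + theta3 * A*M +
#' theta4' C`. The product column is the raw elementwise `A * M` (no
#' centering).
#'
#' @inheritParams fit_mediator_model
#' @return A `model_fit` with coefficients `(Intercept)`, `A`, `M`, `A:M`,
#'   then the covariate columns.
#' @export
fit_outcome_model <- function(dataset, snp, cpg, mode = "auto") {
  M <- dataset$M[, cpg]
  if (anyNA(M)) stop("mediator has missing values; use the mediation sample")
  A <- dataset$A[, snp]
  X <- cbind("(Intercept)" = 1, A = A, M = M, "A:M" = A * M, dataset$C)
  fit_model(X, dataset$Y, dataset$kinship, mode)
}

#' Natural indirect effect with delta-method standard error
#'
#' For the exposure contrast `a` vs `a_star`, the NIE under the mediator and
#' outcome models is `beta1 * (theta2 + theta3 * a) * (a - a_star)`; at the
#' default one-allele contrast (a = 1, a* = 0) this is
#' `beta1 * (theta2 + theta3)`. The standard error is `sqrt(G S G')` where
#' `G` is the gradient of the NIE in the stacked parameter vector
#' `(beta0, beta1, beta2', theta0, theta1, theta2, theta3, theta4')` — at
#' the default contrast `(0, theta2 + theta3, 0', 0, 0, beta1, beta1, 0')` —
#' and `S` is the block-diagonal covariance matrix assembled from the two
#' model fits (cross-model covariances set to zero). The Wald test refers
#' `nie / se` to the standard normal.
#'
#' @param mediator_fit `model_fit` from [fit_mediator_model()].
#' @param outcome_fit `model_fit` from [fit_outcome_model()].
#' @param a,a_star exposure contrast (defaults 1 vs 0).
#' @return An object of class `nie_result`: list with `nie`, `se`, `z`, `p`,
#'   `gradient`, `sigma`, `a`, `a_star`.
#' @export
estimate_nie <- function(mediator_fit, outcome_fit, a = 1, a_star = 0) {
  stopifnot(inherits(mediator_fit, "model_fit"),
            inherits(outcome_fit, "model_fit"))
  bn <- names(mediator_fit$coefficients)
  tn <- names(outcome_fit$coefficients)
  if (!all(c("(Intercept)", "A") %in% bn) ||
      !all(c("(Intercept)", "A", "M", "A:M") %in% tn))
    stop("fits do not look like mediator/outcome model fits")
  if (length(bn) - 2 != length(tn) - 4)
    stop("mediator and outcome fits have different covariate sets")
  beta1 <- mediator_fit$coefficients[["A"]]
  theta2 <- outcome_fit$coefficients[["M"]]
  theta3 <- outcome_fit$coefficients[["A:M"]]
  d <- a - a_star
  nie <- beta1 * (theta2 + theta3 * a) * d

  p1 <- length(bn); p2 <- length(tn)
  grad <- numeric(p1 + p2)
  grad[match("A", bn)] <- (theta2 + theta3 * a) * d
  grad[p1 + match("M", tn)] <- beta1 * d
  grad[p1 + match("A:M", tn)] <- beta1 * a * d
  sigma <- matrix(0, p1 + p2, p1 + p2)
  sigma[seq_len(p1), seq_len(p1)] <- mediator_fit$vcov
  sigma[p1 + seq_len(p2), p1 + seq_len(p2)] <- outcome_fit$vcov
  se <- sqrt(as.numeric(grad %*% sigma %*% grad))
  z <- if (se > 0) nie / se else NA_real_
  structure(list(nie = nie, se = se, z = z,
                 p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
                 gradient = grad, sigma = sigma, a = a, a_star = a_star),
            class = "nie_result")
}

#' @export
print.nie_result <- function(x, ...) {
  cat(sprintf("NIE (a = %g vs a* = %g): %.4g (SE %.4g, z = %.3f, p = %.3g)\n",
              x$a, x$a_star, x$nie, x$se, x$z, x$p))
  invisible(x)
}

#' Wald test for gene-methylation interaction
#'
#' Tests the null `theta3 = 0` (the effect of methylation change on the
#' outcome is the same at every genotype) from the outcome-model fit.
#'
#' @param outcome_fit `model_fit` from [fit_outcome_model()].
#' @return One-row data.frame with `term`, `estimate`, `se`, `z`, `p`, `n`.
#' @export
test_interaction <- function(outcome_fit) {
  wald_row(outcome_fit, "A:M", "A:M")
}

#' Methylation effects stratified by genotype
#'
#' Within each genotype stratum (0, 1 or 2 alternate alleles), regresses the
#' outcome on methylation change and covariates; under the outcome model the
#' stratum-`a` slope is `theta2 + theta3 * a`. Strata smaller than
#' `min_n` (default: covariate count + 3, so the residual has at least one
#' degree of freedom beyond the fitted terms) are reported absent with a
#' warning.
#'
#' @inheritParams fit_mediator_model
#' @param min_n minimum stratum size to attempt a fit.
#' @return data.frame with one row per available stratum: `genotype`, `n`,
#'   `beta`, `se`, `p`.
#' @export
stratified_methylation_effects <- function(dataset, snp, cpg,
                                           min_n = ncol(dataset$C) + 3) {
  A <- dataset$A[, snp]
  M <- dataset$M[, cpg]
  out <- NULL
  for (a in 0:2) {
    idx <- which(A == a)
    if (length(idx) < min_n) {
      warning("genotype stratum ", a, " has ", length(idx),
              " samples (< ", min_n, "); omitted")
      next
    }
    X <- cbind("(Intercept)" = 1, M = M[idx], dataset$C[idx, , drop = FALSE])
    # drop covariate columns constant within the stratum (e.g. one center)
    keep <- c(TRUE, TRUE, apply(dataset$C[idx, , drop = FALSE], 2,
                                function(v) stats::var(v) > 0))
    fit <- fit_ols(X[, keep, drop = FALSE], dataset$Y[idx])
    r <- wald_row(fit, "M")
    out <- rbind(out, data.frame(genotype = a, n = length(idx),
                                 beta = r$estimate, se = r$se, p = r$p))
  }
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha <= 1)
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Per-pair mediation-interaction report
#'
#' For each selected SNP-CpG pair, fits the unadjusted total-effect model,
#' the mediator model and the interaction outcome model, and assembles one
#' row per pair with the total effect (TE, the genotype coefficient of the
#' model excluding the mediator), the natural direct effect (NDE, reported
#' as the genotype coefficient `theta1` of the outcome model), the NIE with
#' its delta-method Wald p-value, and the interaction effect `theta3` —
#' together with MAF and SNP-CpG distance in kb.
#'
#' @param dataset mediation `analysis_dataset` (complete cases including the
#'   mediator).
#' @param pairs data.frame of pairs as from [select_pairs()] (columns `snp`,
#'   `cpg`; `distance_bp` recomputed from the dataset positions if absent).
#' @param screen_dataset optional larger screening dataset used for the
#'   total-effect model; defaults to `dataset`.
#' @param mode fitting mode passed to the model fits.
#' @param sort_by `"nie_p"` or `"interaction_p"`; ties broken by snp then
#'   cpg id.
#' @param a,a_star exposure contrast for the NIE.
#' @return data.frame with columns `snp`, `cpg`, `maf`, `chrom`,
#'   `distance_kb`, `te`, `te_p`, `nde`, `nde_p`, `nie`, `nie_p`,
#'   `int_effect`, `int_p`, `n`.
#' @export
mediation_report <- function(dataset, pairs, screen_dataset = dataset,
                             mode = "auto",
                             sort_by = c("nie_p", "interaction_p"),
                             a = 1, a_star = 0) {
  sort_by <- match.arg(sort_by)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    snp <- pairs$snp[i]; cpg <- pairs$cpg[i]
    te <- fit_total_effect(screen_dataset, snp, mode)
    med <- fit_mediator_model(dataset, snp, cpg, mode)
    out <- fit_outcome_model(dataset, snp, cpg, mode)
    nie <- estimate_nie(med, out, a, a_star)
    int <- test_interaction(out)
    nde <- wald_row(out, "A")
    vi <- match(snp, dataset$variants$id)
    sp <- dataset$variants$pos[vi]
    cp <- dataset$cpgs$pos[match(cpg, dataset$cpgs$id)]
    data.frame(snp = snp, cpg = cpg,
               maf = dataset$variants$maf[vi],
               chrom = dataset$variants$chrom[vi],
               distance_kb = abs(sp - cp) / 1000,
               te = te$estimate, te_p = te$p,
               nde = nde$estimate, nde_p = nde$p,
               nie = nie$nie, nie_p = nie$p,
               int_effect = int$estimate, int_p = int$p,
               n = out$n, stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  key <- if (sort_by == "nie_p") rep$nie_p else rep$int_p
  rep[order(key, rep$snp, rep$cpg), , drop = FALSE]
}
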