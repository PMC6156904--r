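# Synthetic cohorts with the exact generative structure assumed by the
# mediator and outcome models, so every downstream stage and the power
# engine can be exercised without access-restricted cohort data.

#' Generative parameters for the synthetic cohort
#'
#' The mediator model is `M = beta0 + beta1*A + beta2'C + e_M` and the
#' outcome model is `Y = theta0 + theta1*A + theta2*M + theta3*A*M +
#' theta4'C + g + e_Y`, where `A` is the additive alternate-allele dosage of
#' a SNP in Hardy-Weinberg equilibrium at the given minor allele frequency,
#' `M` the treatment change in methylation beta value, `Y` the change in
#' log-triglycerides, `C` the covariates (age, sex, center, smoking) and `g`
#' an optional polygenic effect shared within families.
#'
#' Defaults for the focal effects are the point estimates at the locus with
#' the strongest evidence of mediation in the motivating study
#' (`maf = 0.359`, `beta1 = 0.001`, `theta2 = -1.661`, `theta3 = 0.713`);
#' intercepts and covariate effects default to zero and the residual scales
#' to `sigma_m = 0.05` (methylation-change scale) and `sigma_y = 0.40`
#' (log-TG-change scale).
#'
#' @param maf minor allele frequency, in (0, 0.5].
#' @param beta0,beta1 mediator-model intercept and genotype effect.
#' @param beta2 covariate effects on the mediator; scalar (recycled) or a
#'   vector over the covariate design columns (age, sex, center dummies,
#'   smoke).
#' @param theta0,theta1,theta2,theta3 outcome-model intercept, direct
#'   genotype effect, methylation effect and genotype-by-methylation
#'   interaction.
#' @param theta4 covariate effects on the outcome; scalar or vector as
#'   `beta2`.
#' @param sigma_m,sigma_y residual standard deviations of mediator and
#'   outcome (> 0).
#' @param sigma_g polygenic standard deviation (>= 0; 0 for unrelated
#'   samples).
#' @param age_mean,age_sd,p_female,p_smoke,n_centers covariate generators.
#' @return An object of class `generative_params`.
#' @export
generative_params <- function(maf = 0.359,
                              beta0 = 0, beta1 = 0.001, beta2 = 0,
                              theta0 = 0, theta1 = 0, theta2 = -1.661,
                              theta3 = 0.713, theta4 = 0,
                              sigma_m = 0.05, sigma_y = 0.40, sigma_g = 0,
                              age_mean = 48, age_sd = 14,
                              p_female = 0.5, p_smoke = 0.2, n_centers = 2) {
  p <- list(maf = maf, beta0 = beta0, beta1 = beta1, beta2 = beta2,
            theta0 = theta0, theta1 = theta1, theta2 = theta2,
            theta3 = theta3, theta4 = theta4,
            sigma_m = sigma_m, sigma_y = sigma_y, sigma_g = sigma_g,
            age_mean = age_mean, age_sd = age_sd,
            p_female = p_female, p_smoke = p_smoke, n_centers = n_centers)
  validate_params(p)
  structure(p, class = "generative_params")
}

validate_params <- function(p) {
  bad <- character(0)
  if (!(p$maf > 0 && p$maf <= 0.5)) bad <- c(bad, "maf must be in (0, 0.5]")
  if (!(p$sigma_m > 0)) bad <- c(bad, "sigma_m must be > 0")
  if (!(p$sigma_y > 0)) bad <- c(bad, "sigma_y must be > 0")
  if (!(p$sigma_g >= 0)) bad <- c(bad, "sigma_g must be >= 0")
  if (!(p$n_centers >= 1)) bad <- c(bad, "n_centers must be >= 1")
  if (length(bad)) stop("invalid generative parameters: ",
                        paste(bad, collapse = "; "))
  invisible(p)
}

n_cov_cols <- function(p) 3 + (p$n_centers - 1)

expand_cov_effect <- function(b, p, what) {
  k <- n_cov_cols(p)
  if (length(b) == 1) return(rep(b, k))
  if (length(b) != k)
    stop(what, " must have length 1 or ", k, " (covariate design columns)")
  b
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Dosages are i.i.d. with `P(2) = maf^2`, `P(1) = 2*maf*(1-maf)`,
#' `P(0) = (1-maf)^2`, treating the minor allele as the alternate allele.
#'
#' @param n number of samples.
#' @param maf minor allele frequency in (0, 0.5].
#' @param seed optional integer seed for reproducibility.
#' @return Integer vector of dosages in `{0, 1, 2}`.
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  stopifnot(n >= 1)
  if (!(maf > 0 && maf <= 0.5)) stop("maf must be in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  sample(0:2, n, replace = TRUE,
         prob = c((1 - maf)^2, 2 * maf * (1 - maf), maf^2))
}

simulate_covariates <- function(n, p) {
  data.frame(
    age = stats::rnorm(n, p$age_mean, p$age_sd),
    sex = stats::rbinom(n, 1, p$p_female),
    center = factor(paste0("C", sample.int(p$n_centers, n, replace = TRUE)),
                    levels = paste0("C", seq_len(p$n_centers))),
    smoke = stats::rbinom(n, 1, p$p_smoke))
}

#' Simulate a complete analysis dataset
#'
#' Draws genotypes, covariates, methylation change and outcome from the
#' generative model of [generative_params()]. With `family_size > 1` the
#' cohort is organised into sibships of that size sharing a polygenic effect
#' with covariance `sigma_g^2 * 2 * phi` (phi = 0.25 between full siblings),
#' and the matching kinship matrix is attached to the dataset; otherwise all
#' individuals are unrelated and the polygenic term is zero.
#'
#' @param params a [generative_params()].
#' @param n number of samples (>= 2; must be divisible by `family_size`).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param family_size sibship size (1 = unrelated).
#' @return An `analysis_dataset` with one variant (`snp1`) and one CpG site
#'   (`cg1`), with the true parameters stored in `attr(, "params")`.
#' @export
simulate_dataset <- function(params, n, seed = NULL, family_size = 1) {
  stopifnot(inherits(params, "generative_params"), n >= 2)
  validate_params(params)
  if (n %% family_size != 0) stop("family_size must divide n")
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n))

  A <- simulate_genotypes(n, params$maf)
  cov <- simulate_covariates(n, params)
  C <- stats::model.matrix(~ age + sex + center + smoke, cov)[, -1, drop = FALSE]
  rownames(C) <- ids
  b2 <- expand_cov_effect(params$beta2, params, "beta2")
  t4 <- expand_cov_effect(params$theta4, params, "theta4")

  M <- params$beta0 + params$beta1 * A + as.numeric(C %*% b2) +
    stats::rnorm(n, 0, params$sigma_m)

  g <- rep(0, n)
  kin <- NULL
  if (family_size > 1) {
    n_fam <- n / family_size
    fam <- rep(seq_len(n_fam), each = family_size)
    if (params$sigma_g > 0) {
      # siblings: cov(g_i, g_j) = sigma_g^2 * 2*phi_ij = sigma_g^2 / 2
      shared <- stats::rnorm(n_fam)[fam]
      own <- stats::rnorm(n)
      g <- params$sigma_g * sqrt(0.5) * (shared + own)
    }
    phi <- matrix(0, n, n, dimnames = list(ids, ids))
    for (f in seq_len(n_fam)) {
      idx <- which(fam == f)
      phi[idx, idx] <- 0.25
    }
    diag(phi) <- 0.5
    kin <- kinship_matrix(phi)
  }

  Y <- params$theta0 + params$theta1 * A + params$theta2 * M +
    params$theta3 * A * M + as.numeric(C %*% t4) + g +
    stats::rnorm(n, 0, params$sigma_y)

  ds <- new_analysis_dataset(
    sample_ids = ids,
    A = matrix(A, ncol = 1, dimnames = list(ids, "snp1")),
    M = matrix(M, ncol = 1, dimnames = list(ids, "cg1")),
    Y = stats::setNames(Y, ids),
    C = C,
    covariates = cov,
    variants = data.frame(id = "snp1", chrom = "10", pos = 1000000L,
                          ref = "A", alt = "G", maf = dosage_maf(A),
                          stringsAsFactors = FALSE),
    cpgs = data.frame(id = "cg1", chrom = "10", pos = 1012500L,
                      stringsAsFactors = FALSE),
    kinship = kin)
  attr(ds, "params") <- params
  ds
}

#' Monte-Carlo counterfactual oracle for the natural indirect effect
#'
#' Brute-force evaluation of `NIE = E[Y_{a M(a)} - Y_{a M(a*)}]` under the
#' generative model: potential mediators `M(a)` and `M(a*)` are simulated
#' with independent residual draws, plugged into the outcome model at
#' exposure `a`, and the mean difference of the two potential outcomes is
#' returned. Serves as an independent check on the closed form
#' `beta1 * (theta2 + theta3 * a) * (a - a*)`.
#'
#' @param params a [generative_params()].
#' @param a,a_star exposure contrast levels (defaults 1 vs 0, one additional
#'   alternate allele).
#' @param n_draws number of Monte-Carlo draws (>= 1000).
#' @param seed optional integer seed.
#' @return List with `nie` (Monte-Carlo mean), `mc_se` (its standard error)
#'   and `n_draws`.
#' @export
oracle_nie_monte_carlo <- function(params, a = 1, a_star = 0,
                                   n_draws = 100000, seed = NULL) {
  stopifnot(inherits(params, "generative_params"), n_draws >= 1000)
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  cov <- simulate_covariates(n_draws, params)
  C <- stats::model.matrix(~ age + sex + center + smoke, cov)[, -1, drop = FALSE]
  b2 <- expand_cov_effect(params$beta2, params, "beta2")
  ceff <- as.numeric(C %*% b2)
  m_a <- params$beta0 + params$beta1 * a + ceff +
    stats::rnorm(n_draws, 0, params$sigma_m)
  m_astar <- params$beta0 + params$beta1 * a_star + ceff +
    stats::rnorm(n_draws, 0, params$sigma_m)
  # outcome residual, direct effect and covariate terms cancel in the
  # difference of potential outcomes at common exposure a
  diff <- (params$theta2 + params$theta3 * a) * (m_a - m_astar)
  list(nie = mean(diff), mc_se = stats::sd(diff) / sqrt(n_draws),
       n_draws = n_draws)
}

#' Write a synthetic multi-marker study to disk in the pipeline input formats
#'
#' Generates `n_snps` independent SNPs and `n_cpgs` CpG sites for `n`
#' samples, with one designated causal pair (the first SNP and first CpG)
#' following the full generative model and all remaining markers null.
#' Marker positions are laid out on one chromosome so that some null pairs
#' also fall within the pairing radius. Emits a VCF, pre/post methylation
#' TSVs, a CpG position TSV, a phenotype TSV and (for `family_size > 1`) a
#' pedigree-free kinship TSV, i.e. everything [run_pipeline()] consumes.
#'
#' @param dir output directory (created if needed).
#' @param params a [generative_params()].
#' @param n,n_snps,n_cpgs cohort and marker counts.
#' @param seed integer seed.
#' @param family_size sibship size passed to [simulate_dataset()].
#' @param p_missing_post fraction of samples with missing post-treatment
#'   methylation (emulating attrition between the screening and mediation
#'   samples).
#' @param spacing_bp distance between consecutive markers.
#' @return Named list of written file paths.
#' @export
write_study <- function(dir, params = generative_params(), n = 400,
                        n_snps = 50, n_cpgs = 50, seed = 1,
                        family_size = 1, p_missing_post = 0.1,
                        spacing_bp = 20000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(params, n, seed = seed, family_size = family_size)
  ids <- ds$sample_ids
  # causal SNP/CpG from the generative model, null markers on top
  dos <- matrix(0, n, n_snps, dimnames = list(ids, sprintf("rs%05d", seq_len(n_snps))))
  dos[, 1] <- ds$A[, 1]
  for (j in seq_len(n_snps)[-1]) {
    dos[, j] <- simulate_genotypes(n, stats::runif(1, 0.05, 0.5))
  }
  snp_pos <- as.integer(seq(1e6, by = 2 * spacing_bp, length.out = n_snps))
  variants <- data.frame(id = colnames(dos), chrom = "10", pos = snp_pos,
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  geno <- genotype_matrix(dos, variants)

  delta <- matrix(stats::rnorm(n * n_cpgs, 0, params$sigma_m), n, n_cpgs,
                  dimnames = list(ids, sprintf("cg%07d", seq_len(n_cpgs))))
  delta[, 1] <- ds$M[, 1]
  pre <- matrix(stats::runif(n * n_cpgs, 0.3, 0.7), n, n_cpgs,
                dimnames = dimnames(delta))
  post <- pmin(pmax(pre + delta, 0), 1)
  # attrition: whole samples lose the post-treatment array
  drop <- sample(ids, round(p_missing_post * n))
  post[drop, ] <- NA_real_
  cpg_pos <- as.integer(snp_pos + spacing_bp / 2)
  cpgs <- data.frame(id = colnames(delta), chrom = "10",
                     pos = cpg_pos[seq_len(n_cpgs)], stringsAsFactors = FALSE)
  meth <- methylation_panel(pre, post, cpgs)

  tg_pre <- exp(stats::rnorm(n, log(120), 0.35))
  tg_post <- tg_pre * exp(ds$Y)
  pheno <- phenotype_table(data.frame(
    sample_id = ids, tg_pre = tg_pre, tg_post = tg_post,
    ds$covariates, stringsAsFactors = FALSE))

  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    meth_pre = file.path(dir, "methylation_pre.tsv"),
    meth_post = file.path(dir, "methylation_post.tsv"),
    cpg_positions = file.path(dir, "cpg_positions.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"))
  write_genotypes_vcf(geno, paths$vcf)
  write_methylation_tsv(meth, paths$meth_pre, paths$meth_post,
                        paths$cpg_positions)
  write_phenotypes_tsv(pheno, paths$phenotypes)
  if (!is.null(ds$kinship)) {
    paths$kinship <- file.path(dir, "kinship.tsv")
    write_kinship_tsv(ds$kinship, paths$kinship)
  }
  paths
}
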