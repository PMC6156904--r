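# Marginal phenotype models for SNPs (total effect) and CpG sites (EWAS),
# and the three-criterion selection of proximal SNP-CpG candidate pairs.

#' Marginal total effect of a SNP on the outcome
#'
#' Fits `E(Y | A, C) = gamma0 + gamma1 * A + gamma2' C` (the model excluding
#' the mediator) and returns the Wald test for the genotype coefficient
#' `gamma1`, the total effect of the SNP.
#'
#' @param dataset an `analysis_dataset` (screening sample: complete for
#'   genotype, outcome and covariates).
#' @param variant variant id (a column of `dataset$A`).
#' @param mode fitting mode: `"auto"` (LMM when kinship is attached, else
#'   OLS), `"ols"`, or `"lmm"`.
#' @return One-row data.frame with `term`, `estimate`, `se`, `z`, `p`, `n`,
#'   or `NULL` (with a warning) for a monomorphic variant.
#' @export
fit_total_effect <- function(dataset, variant, mode = "auto") {
  A <- dataset$A[, variant]
  if (length(unique(A)) < 2) {
    warning("variant ", variant, " is monomorphic; skipped")
    return(NULL)
  }
  X <- cbind("(Intercept)" = 1, A = A, dataset$C)
  wald_row(fit_model(X, dataset$Y, dataset$kinship, mode), "A", variant)
}

#' Marginal association of methylation change with the outcome
#'
#' Fits `E(Y | M, C) = eta0 + eta1 * M + eta2' C` and returns the Wald test
#' for the methylation-change coefficient `eta1` (the EWAS model).
#'
#' @param dataset an `analysis_dataset` complete for the mediator.
#' @param cpg CpG id (a column of `dataset$M`).
#' @inheritParams fit_total_effect
#' @return One-row data.frame as [fit_total_effect()], or `NULL` for a
#'   constant methylation change.
#' @export
fit_marginal_methylation <- function(dataset, cpg, mode = "auto") {
  M <- dataset$M[, cpg]
  if (anyNA(M)) stop("methylation change for ", cpg, " has missing values; ",
                     "use the mediation (complete-mediator) sample")
  if (length(unique(M)) < 2) {
    warning("CpG ", cpg, " has constant methylation change; skipped")
    return(NULL)
  }
  X <- cbind("(Intercept)" = 1, M = M, dataset$C)
  wald_row(fit_model(X, dataset$Y, dataset$kinship, mode), "M", cpg)
}

#' Screen all variants and CpG sites marginally
#'
#' Convenience loop applying [fit_total_effect()] to every variant of the
#' screening dataset and [fit_marginal_methylation()] to every CpG of the
#' mediation dataset.
#'
#' @param screen_ds screening `analysis_dataset` (genotype/outcome complete).
#' @param med_ds mediation `analysis_dataset` (mediator also complete);
#'   defaults to `screen_ds`.
#' @inheritParams fit_total_effect
#' @return List with data.frames `snps` and `cpgs`.
#' @export
screen_all <- function(screen_ds, med_ds = screen_ds, mode = "auto") {
  snps <- do.call(rbind, lapply(colnames(screen_ds$A), function(v)
    fit_total_effect(screen_ds, v, mode)))
  cpgs <- do.call(rbind, lapply(colnames(med_ds$M), function(cg)
    fit_marginal_methylation(med_ds, cg, mode)))
  list(snps = snps, cpgs = cpgs)
}

#' Select proximal SNP-CpG candidate pairs
#'
#' Applies the three selection criteria, each as a strict inequality: SNP
#' marginal p-value below `p_snp_max`, CpG marginal p-value below
#' `p_cpg_max`, and SNP-CpG distance below `radius_bp` on the same
#' chromosome. A SNP may pair with several CpG sites and vice versa.
#'
#' @param snp_results data.frame with columns `term` (variant id) and `p`,
#'   as returned by [fit_total_effect()] / [screen_all()].
#' @param cpg_results data.frame with columns `term` (CpG id) and `p`.
#' @param snp_positions data.frame `id`, `chrom`, `pos` for the SNPs.
#' @param cpg_positions data.frame `id`, `chrom`, `pos` for the CpGs.
#' @param p_snp_max,p_cpg_max,radius_bp selection thresholds (defaults:
#'   1e-3, 0.05, 50 kb).
#' @return data.frame with one row per retained pair: `snp`, `cpg`, `chrom`,
#'   `distance_bp`, `snp_p`, `cpg_p`, ordered by snp then cpg id.
#' @export
select_pairs <- function(snp_results, cpg_results, snp_positions,
                         cpg_positions, p_snp_max = 1e-3, p_cpg_max = 0.05,
                         radius_bp = 50000) {
  empty <- data.frame(snp = character(0), cpg = character(0),
                      chrom = character(0), distance_bp = numeric(0),
                      snp_p = numeric(0), cpg_p = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(snp_results) || is.null(cpg_results) ||
      !nrow(snp_results) || !nrow(cpg_results)) return(empty)
  drop_unplaced <- function(res, positions, what) {
    miss <- !(res$term %in% positions$id)
    if (any(miss))
      warning("no position for ", what, ": ",
              paste(res$term[miss], collapse = ", "), "; excluded")
    res[!miss, , drop = FALSE]
  }
  snp_results <- drop_unplaced(snp_results, snp_positions, "SNP(s)")
  cpg_results <- drop_unplaced(cpg_results, cpg_positions, "CpG(s)")
  snps <- snp_results[snp_results$p < p_snp_max, , drop = FALSE]
  cpgs <- cpg_results[cpg_results$p < p_cpg_max, , drop = FALSE]
  if (!nrow(snps) || !nrow(cpgs)) return(empty)
  out <- empty
  for (i in seq_len(nrow(snps))) {
    sp <- snp_positions[snp_positions$id == snps$term[i], ]
    for (j in seq_len(nrow(cpgs))) {
      cp <- cpg_positions[cpg_positions$id == cpgs$term[j], ]
      if (as.character(sp$chrom) != as.character(cp$chrom)) next
      dist <- abs(sp$pos - cp$pos)
      if (dist >= radius_bp) next
      out <- rbind(out, data.frame(
        snp = snps$term[i], cpg = cpgs$term[j],
        chrom = as.character(sp$chrom), distance_bp = dist,
        snp_p = snps$p[i], cpg_p = cpgs$p[j], stringsAsFactors = FALSE))
    }
  }
  out[order(out$snp, out$cpg), , drop = FALSE]
}
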