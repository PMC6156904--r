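# End-to-end orchestration: read inputs, screen markers, select pairs,
# run the mediation-interaction analysis, and write reports plus a manifest.

#' Build a pipeline run configuration
#'
#' @param vcf,meth_pre,meth_post,cpg_positions,phenotypes input file paths
#'   in the formats documented in the io readers.
#' @param kinship optional kinship TSV path ([read_kinship()] format).
#' @param out_dir output directory.
#' @param p_snp_max,p_cpg_max,radius_bp pair-selection thresholds.
#' @param alpha nominal level used for the Bonferroni threshold reported in
#'   the manifest.
#' @param mode fitting mode: `"auto"`, `"ols"` or `"lmm"`.
#' @param a,a_star exposure contrast for the NIE.
#' @param seed integer seed recorded in the manifest (the analysis itself is
#'   deterministic given the inputs).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(vcf, meth_pre, meth_post, cpg_positions, phenotypes,
                       kinship = NULL, out_dir = "methmedint_out",
                       p_snp_max = 1e-3, p_cpg_max = 0.05, radius_bp = 50000,
                       alpha = 0.05, mode = "auto", a = 1, a_star = 0,
                       seed = 1) {
  stopifnot(p_snp_max > 0, p_cpg_max > 0, radius_bp > 0, alpha > 0)
  mode <- match.arg(mode, c("auto", "ols", "lmm"))
  structure(list(vcf = vcf, meth_pre = meth_pre, meth_post = meth_post,
                 cpg_positions = cpg_positions, phenotypes = phenotypes,
                 kinship = kinship, out_dir = out_dir,
                 p_snp_max = p_snp_max, p_cpg_max = p_cpg_max,
                 radius_bp = radius_bp, alpha = alpha, mode = mode,
                 a = a, a_star = a_star, seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Write a pipeline configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))],
                   path)
  invisible(path)
}

# write df to path atomically: a failed stage leaves a .partial file only
write_stage_tsv <- function(df, path) {
  tmp <- paste0(path, ".partial")
  write_tsv(df, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full screening / selection / mediation pipeline
#'
#' Stages: read and align inputs (screening sample = complete genotype,
#' outcome and covariates; mediation sample = additionally complete
#' methylation change), marginal screening of every SNP and CpG, selection
#' of proximal significant pairs, and per-pair mediation-interaction
#' analysis. Writes `snp_screen.tsv`, `cpg_screen.tsv`, `pairs.tsv`,
#' `mediation_report.tsv` (sorted by NIE p-value),
#' `interaction_report.tsv` (sorted by interaction p-value),
#' `stratified_effects.tsv` for pairs passing the Bonferroni-corrected
#' interaction threshold, and `manifest.yaml` with counts, thresholds, seed
#' and package version.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the manifest and the report data.frames.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- stage("read", {
    list(geno = read_genotypes(config$vcf),
         meth = read_methylation(config$meth_pre, config$meth_post,
                                 config$cpg_positions),
         pheno = read_phenotypes(config$phenotypes),
         kin = if (is.null(config$kinship)) NULL else
           read_kinship(config$kinship))
  })
  screen_ds <- stage("align", align_complete_cases(
    inputs$geno, inputs$meth, inputs$pheno, inputs$kin,
    require_mediator = FALSE))
  med_ds <- stage("align", align_complete_cases(
    inputs$geno, inputs$meth, inputs$pheno, inputs$kin,
    require_mediator = TRUE))

  scr <- stage("screen", screen_all(screen_ds, med_ds, mode = config$mode))
  write_stage_tsv(annotate_positions(scr$snps, screen_ds$variants),
                  file.path(config$out_dir, "snp_screen.tsv"))
  write_stage_tsv(annotate_positions(scr$cpgs, med_ds$cpgs),
                  file.path(config$out_dir, "cpg_screen.tsv"))

  pairs <- stage("select", select_pairs(
    scr$snps, scr$cpgs, screen_ds$variants, med_ds$cpgs,
    p_snp_max = config$p_snp_max, p_cpg_max = config$p_cpg_max,
    radius_bp = config$radius_bp))
  write_stage_tsv(pairs, file.path(config$out_dir, "pairs.tsv"))

  med_report <- int_report <- strat <- NULL
  bonf <- bonferroni_threshold(config$alpha, max(1, nrow(pairs)))
  if (nrow(pairs)) {
    med_report <- stage("mediate", mediation_report(
      med_ds, pairs, screen_dataset = screen_ds, mode = config$mode,
      sort_by = "nie_p", a = config$a, a_star = config$a_star))
    int_report <- med_report[order(med_report$int_p, med_report$snp,
                                   med_report$cpg), , drop = FALSE]
    write_stage_tsv(med_report,
                    file.path(config$out_dir, "mediation_report.tsv"))
    write_stage_tsv(int_report,
                    file.path(config$out_dir, "interaction_report.tsv"))
    hits <- int_report[int_report$int_p < bonf, , drop = FALSE]
    if (nrow(hits)) {
      strat <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i)
        cbind(snp = hits$snp[i], cpg = hits$cpg[i],
              stratified_methylation_effects(med_ds, hits$snp[i],
                                             hits$cpg[i]))))
      write_stage_tsv(strat,
                      file.path(config$out_dir, "stratified_effects.tsv"))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("methmedint")),
    seed = config$seed, mode = config$mode,
    thresholds = list(p_snp_max = config$p_snp_max,
                      p_cpg_max = config$p_cpg_max,
                      radius_bp = config$radius_bp, alpha = config$alpha,
                      bonferroni = bonf),
    counts = list(
      samples_screening = length(screen_ds$sample_ids),
      samples_mediation = length(med_ds$sample_ids),
      snps_tested = if (is.null(scr$snps)) 0L else nrow(scr$snps),
      cpgs_tested = if (is.null(scr$cpgs)) 0L else nrow(scr$cpgs),
      pairs_selected = nrow(pairs),
      interaction_hits = if (is.null(int_report)) 0L else
        sum(int_report$int_p < bonf)))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(list(manifest = manifest, pairs = pairs,
                 mediation_report = med_report,
                 interaction_report = int_report,
                 stratified = strat))
}

annotate_positions <- function(res, positions) {
  if (is.null(res)) return(data.frame())
  i <- match(res$term, positions$id)
  cbind(id = res$term, chrom = positions$chrom[i], pos = positions$pos[i],
        res[, c("estimate", "se", "z", "p", "n")])
}
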