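# Readers, writers and alignment of genotype / methylation / phenotype /
# pedigree inputs into a complete-case analysis dataset.

#' Construct a genotype matrix
#'
#' Holds additive alternate-allele dosages (0, 1, 2 or `NA`) for a set of
#' samples and biallelic variants, together with variant positions and minor
#' allele frequencies computed from the non-missing dosages.
#'
#' @param dosages numeric matrix, samples in rows (rownames = sample ids),
#'   variants in columns (colnames = variant ids); entries in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`;
#'   one row per dosage column, `pos` 1-based and strictly positive.
#' @return An object of class `genotype_matrix` with elements `sample_ids`,
#'   `dosages`, `variants` (gains a `maf` column).
#' @export
genotype_matrix <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  stopifnot(is.numeric(dosages), !is.null(rownames(dosages)),
            !is.null(colnames(dosages)))
  if (!all(dosages %in% c(0, 1, 2) | is.na(dosages)))
    stop("dosages must be 0, 1, 2 or NA")
  variants <- as.data.frame(variants)
  req <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants)))
    stop("variants needs columns: ", paste(req, collapse = ", "))
  if (!identical(as.character(variants$id), colnames(dosages)))
    stop("variant ids must match dosage column names, in order")
  if (any(variants$pos <= 0)) stop("variant positions must be positive")
  variants$maf <- apply(dosages, 2, dosage_maf)
  structure(list(sample_ids = rownames(dosages),
                 dosages = dosages,
                 variants = variants),
            class = "genotype_matrix")
}

# alt-allele frequency folded onto [0, 0.5]
dosage_maf <- function(d) {
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  p <- mean(d) / 2
  min(p, 1 - p)
}

#' Read genotypes from a VCF file
#'
#' Parses the GT field of a VCF into additive alternate-allele dosages.
#' Multiallelic records are skipped with a warning; missing genotypes
#' (`./.` or `.`) become `NA`.
#'
#' @param path path to a (possibly bgzipped) VCF file.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped: ",
            paste(utils::head(fix$ID[multi], 5), collapse = ", "))
  }
  keep <- !multi
  if (!any(keep)) stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  dos <- apply(gt, c(1, 2), gt_to_dosage)
  dos <- t(dos)  # samples x variants
  colnames(dos) <- ids
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants)
}

gt_to_dosage <- function(g) {
  if (is.na(g)) return(NA_real_)
  alleles <- strsplit(g, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles == "1")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a methylation panel
#'
#' Pre- and post-treatment beta values per CpG site, with the treatment
#' change `delta = post - pre` computed wherever both are observed.
#'
#' @param pre,post numeric matrices, samples in rows, CpG sites in columns,
#'   beta values in `[0, 1]`; the two sample sets may differ (missing entries
#'   are `NA`).
#' @param cpgs data.frame with columns `id`, `chrom`, `pos` for each column.
#' @return An object of class `methylation_panel` with `pre`, `post`,
#'   `delta`, `cpgs`, `sample_ids`.
#' @export
methylation_panel <- function(pre, post, cpgs) {
  samples <- union(rownames(pre), rownames(post))
  ids <- colnames(pre)
  if (!identical(ids, colnames(post)))
    stop("pre and post matrices must cover the same CpG sites")
  cpgs <- as.data.frame(cpgs)
  if (!all(c("id", "chrom", "pos") %in% names(cpgs)))
    stop("cpgs needs columns id, chrom, pos")
  if (!setequal(cpgs$id, ids)) stop("cpg position table does not match matrices")
  cpgs <- cpgs[match(ids, cpgs$id), , drop = FALSE]
  pre <- expand_to_samples(pre, samples)
  post <- expand_to_samples(post, samples)
  check_beta(pre, "pre")
  check_beta(post, "post")
  structure(list(sample_ids = samples, cpgs = cpgs,
                 pre = pre, post = post, delta = post - pre),
            class = "methylation_panel")
}

expand_to_samples <- function(m, samples) {
  out <- matrix(NA_real_, length(samples), ncol(m),
                dimnames = list(samples, colnames(m)))
  out[rownames(m), ] <- as.matrix(m)
  out
}

check_beta <- function(m, label) {
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("beta value outside [0,1] in ", label, " matrix at CpG ",
         colnames(m)[bad[1, 2]], ", sample ", rownames(m)[bad[1, 1]])
  }
}

#' Read pre/post methylation matrices from TSV files
#'
#' Each matrix file is tab-separated with CpG ids in the first column and one
#' column per sample; the positions file has columns `id`, `chrom`, `pos`.
#'
#' @param pre_path,post_path paths to the CpG x sample beta-value matrices.
#' @param positions_path path to the 3-column CpG position table.
#' @return A [methylation_panel()].
#' @export
read_methylation <- function(pre_path, post_path, positions_path) {
  read_mat <- function(p) {
    d <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    t(m)  # samples x CpGs
  }
  pre <- read_mat(pre_path)
  post <- read_mat(post_path)
  cpgs <- utils::read.delim(positions_path, stringsAsFactors = FALSE)
  methylation_panel(pre, post, cpgs)
}

#' Construct a phenotype/covariate table
#'
#' Computes the outcome `y = log(tg_post) - log(tg_pre)` (natural log of the
#' post/pre triglyceride ratio) and validates covariates.
#'
#' @param df data.frame with columns `sample_id`, `tg_pre`, `tg_post` (mg/dL,
#'   strictly positive where present), `age`, `sex` (0/1), `center`
#'   (categorical), `smoke` (0/1).
#' @return An object of class `phenotype_table`: the input plus a `y` column,
#'   with `center` coerced to factor.
#' @export
phenotype_table <- function(df) {
  df <- as.data.frame(df)
  req <- c("sample_id", "tg_pre", "tg_post", "age", "sex", "center", "smoke")
  if (!all(req %in% names(df)))
    stop("phenotype table needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids")
  for (col in c("tg_pre", "tg_post")) {
    bad <- !is.na(df[[col]]) & df[[col]] <= 0
    if (any(bad))
      stop("nonpositive ", col, " for sample(s): ",
           paste(utils::head(df$sample_id[bad], 5), collapse = ", "))
  }
  if (!all(df$sex %in% c(0, 1, NA))) stop("sex must be coded 0/1")
  if (!all(df$smoke %in% c(0, 1, NA))) stop("smoke must be coded 0/1")
  df$center <- factor(df$center)
  df$y <- log(df$tg_post) - log(df$tg_pre)
  structure(df, class = c("phenotype_table", "data.frame"))
}

#' Read a phenotype/covariate TSV
#'
#' @param path tab-separated file with the columns documented in
#'   [phenotype_table()].
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  phenotype_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

# Covariate design matrix (no intercept column): age, sex, center dummies
# (first level as reference), smoke. Errors if rank-deficient.
covariate_design <- function(pheno) {
  mm <- stats::model.matrix(~ age + sex + center + smoke,
                            data = as.data.frame(pheno))
  X <- mm[, -1, drop = FALSE]
  rownames(X) <- pheno$sample_id[as.integer(rownames(mm))]
  X
}

#' Construct a kinship matrix object
#'
#' @param phi symmetric numeric matrix of kinship coefficients with sample ids
#'   as dimnames; the relationship matrix used in model fitting is `2 * phi`.
#' @return An object of class `kinship_matrix`.
#' @export
kinship_matrix <- function(phi) {
  phi <- as.matrix(phi)
  if (is.null(rownames(phi))) stop("phi needs sample ids as dimnames")
  if (!isSymmetric(unname(phi), tol = 1e-10)) stop("phi must be symmetric")
  structure(list(sample_ids = rownames(phi), phi = phi),
            class = "kinship_matrix")
}

#' Kinship coefficients from a pedigree
#'
#' Computes the kinship matrix by the standard recursive algorithm:
#' phi(i,i) = (1 + phi(father, mother)) / 2 and
#' phi(i,j) = (phi(father, j) + phi(mother, j)) / 2 for j not a descendant
#' of i, processing individuals in generation order. Founders are non-inbred
#' (self-kinship 0.5); full siblings and parent-offspring pairs get 0.25.
#'
#' @param ped data.frame or path to a whitespace-separated pedigree file with
#'   columns `fid`, `iid`, `father`, `mother`, `sex` ("0" = founder parent).
#' @return A [kinship_matrix()] over all pedigree members.
#' @export
kinship_from_pedigree <- function(ped) {
  if (is.character(ped)) {
    ped <- utils::read.table(ped, header = TRUE, stringsAsFactors = FALSE,
                             colClasses = "character")
  }
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  if (!all(c("iid", "father", "mother") %in% names(ped)))
    stop("pedigree needs columns iid, father, mother")
  id <- as.character(ped$iid)
  fa <- as.character(ped$father)
  mo <- as.character(ped$mother)
  fa[fa %in% c("0", "", NA)] <- NA
  mo[mo %in% c("0", "", NA)] <- NA
  if (anyDuplicated(id)) stop("duplicated individual ids in pedigree")
  unknown <- setdiff(stats::na.omit(c(fa, mo)), id)
  if (length(unknown))
    stop("unknown parent id(s): ", paste(unknown, collapse = ", "))
  n <- length(id)
  # topological order: repeatedly emit individuals whose parents are placed
  placed <- rep(FALSE, n)
  order_idx <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(fa) | fa %in% id[placed]) &
      (is.na(mo) | mo %in% id[placed])
    if (!any(ready)) break
    order_idx <- c(order_idx, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) stop("cyclic pedigree involving: ",
                         paste(id[!placed], collapse = ", "))
  phi <- matrix(0, n, n, dimnames = list(id, id))
  done <- integer(0)
  for (i in order_idx) {
    f <- fa[i]; m <- mo[i]
    for (j in done) {
      pf <- if (is.na(f)) 0 else phi[f, j]
      pm <- if (is.na(m)) 0 else phi[m, j]
      phi[i, j] <- phi[j, i] <- 0.5 * (pf + pm)
    }
    inb <- if (is.na(f) || is.na(m)) 0 else phi[f, m]
    phi[i, i] <- 0.5 * (1 + inb)
    done <- c(done, i)
  }
  kinship_matrix(phi)
}

#' Read a precomputed kinship matrix from a square TSV
#'
#' @param path tab-separated file with a header row of sample ids and the same
#'   ids in the first column.
#' @return A [kinship_matrix()].
#' @export
read_kinship <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  kinship_matrix(m)
}

#' Align inputs into a complete-case analysis dataset
#'
#' Intersects the sample sets of the genotype, methylation and phenotype
#' inputs and keeps samples with complete data for the analysis at hand:
#' with `require_mediator = FALSE` completeness is required for genotypes,
#' outcome and covariates (the screening sample); with `TRUE` additionally
#' for the methylation change at every CpG (the mediation sample, a subset of
#' the screening sample).
#'
#' @param geno a [genotype_matrix()].
#' @param meth a [methylation_panel()].
#' @param pheno a [phenotype_table()].
#' @param kinship optional [kinship_matrix()]; subset to retained samples.
#' @param require_mediator logical; require complete methylation change.
#' @return An object of class `analysis_dataset` with elements `sample_ids`,
#'   `A` (dosage matrix), `M` (methylation-change matrix, screening sample may
#'   contain `NA`), `Y`, `C` (covariate design matrix), `covariates`,
#'   `variants`, `cpgs`, `kinship` (or `NULL`).
#' @export
align_complete_cases <- function(geno, meth, pheno, kinship = NULL,
                                 require_mediator = TRUE) {
  stopifnot(inherits(geno, "genotype_matrix"),
            inherits(meth, "methylation_panel"),
            inherits(pheno, "phenotype_table"))
  ids <- Reduce(intersect, list(geno$sample_ids, meth$sample_ids,
                                as.character(pheno$sample_id)))
  if (!is.null(kinship)) ids <- intersect(ids, kinship$sample_ids)
  if (!length(ids)) stop("no samples common to all inputs")
  ph <- as.data.frame(pheno)[match(ids, pheno$sample_id), , drop = FALSE]
  C <- covariate_design(phenotype_table(ph))
  A <- geno$dosages[ids, , drop = FALSE]
  M <- meth$delta[ids, , drop = FALSE]
  ok <- stats::complete.cases(A) & !is.na(ph$y) & stats::complete.cases(C)
  if (require_mediator) ok <- ok & stats::complete.cases(M)
  ids <- ids[ok]
  if (!length(ids)) stop("no complete cases after alignment")
  new_analysis_dataset(
    sample_ids = ids,
    A = A[ok, , drop = FALSE],
    M = M[ok, , drop = FALSE],
    Y = stats::setNames(ph$y[ok], ids),
    C = C[ok, , drop = FALSE],
    covariates = ph[ok, c("age", "sex", "center", "smoke"), drop = FALSE],
    variants = geno$variants,
    cpgs = meth$cpgs,
    kinship = if (is.null(kinship)) NULL else
      kinship_matrix(kinship$phi[ids, ids, drop = FALSE]))
}

new_analysis_dataset <- function(sample_ids, A, M, Y, C, covariates,
                                 variants, cpgs, kinship = NULL) {
  structure(list(sample_ids = sample_ids, A = A, M = M, Y = Y, C = C,
                 covariates = covariates, variants = variants, cpgs = cpgs,
                 kinship = kinship),
            class = "analysis_dataset")
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat("analysis_dataset:", length(x$sample_ids), "samples,",
      ncol(x$A), "variant(s),", ncol(x$M), "CpG site(s),",
      if (is.null(x$kinship)) "no kinship\n" else "with kinship\n")
  invisible(x)
}

# ---- writers (used by the synthetic-data study emitter and the pipeline) ----

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits unphased GT calls (`0/0`, `0/1`, `1/1`, `./.`) for round-tripping
#' through [read_genotypes()].
#'
#' @param geno a [genotype_matrix()].
#' @param path output path (plain-text VCF).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path) {
  v <- geno$variants
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", geno$sample_ids), collapse = "\t"))
  for (j in seq_len(nrow(v))) {
    d <- geno$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1])
    lines <- c(lines, paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j],
                              v$alt[j], ".", "PASS", ".", "GT", gt),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a methylation panel to pre/post/position TSV files
#'
#' @param meth a [methylation_panel()].
#' @param pre_path,post_path,positions_path output paths.
#' @return The three paths, invisibly.
#' @export
write_methylation_tsv <- function(meth, pre_path, post_path, positions_path) {
  dump_mat <- function(m, path) {
    df <- data.frame(cpg = colnames(m), t(m), check.names = FALSE)
    write_tsv(df, path)
  }
  # drop all-NA samples from each matrix so sample sets can differ on re-read
  keep_pre <- rowSums(!is.na(meth$pre)) > 0
  keep_post <- rowSums(!is.na(meth$post)) > 0
  dump_mat(meth$pre[keep_pre, , drop = FALSE], pre_path)
  dump_mat(meth$post[keep_post, , drop = FALSE], post_path)
  write_tsv(meth$cpgs[, c("id", "chrom", "pos")], positions_path)
  invisible(c(pre_path, post_path, positions_path))
}

#' Write a phenotype table to TSV
#'
#' @param pheno a [phenotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes_tsv <- function(pheno, path) {
  df <- as.data.frame(pheno)
  write_tsv(df[, c("sample_id", "tg_pre", "tg_post", "age", "sex",
                   "center", "smoke")], path)
}

#' Write a kinship matrix to a square TSV
#'
#' @param kin a [kinship_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kinship_tsv <- function(kin, path) {
  df <- data.frame(sample_id = kin$sample_ids, kin$phi, check.names = FALSE)
  write_tsv(df, path)
}
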