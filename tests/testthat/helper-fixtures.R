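# Shared fixture builders: everything is generated in code at test time.

# 10-sample, 2-variant VCF (second record multiallelic, to be skipped)
write_fixture_vcf <- function(path, dosages = c(0, 0, 1, 1, 1, 2, 0, 1, 2, 0),
                              with_multiallelic = TRUE,
                              with_missing = FALSE) {
  samples <- sprintf("S%02d", seq_along(dosages))
  gt <- c("0/0", "0/1", "1/1")[dosages + 1]
  if (with_missing) gt[1] <- "./."
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    paste(c("10", "1000", "rs1", "A", "G", ".", "PASS", ".", "GT", gt),
          collapse = "\t"))
  if (with_multiallelic) {
    lines <- c(lines, paste(c("10", "2000", "rs2", "A", "G,T", ".", "PASS",
                              ".", "GT", rep("0/0", length(samples))),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

toy_phenotypes <- function(n = 6) {
  data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    tg_pre = rep(c(100, 200, 150), length.out = n),
    tg_post = rep(c(100, 100, 180), length.out = n),
    age = seq(30, by = 2, length.out = n),
    sex = rep(c(0, 1), length.out = n),
    center = rep(c("A", "B"), length.out = n),
    smoke = rep(c(0, 0, 1), length.out = n))
}

# hand-built model_fit objects for formula-level NIE checks
manual_fit <- function(coefs, vc) {
  dimnames(vc) <- list(names(coefs), names(coefs))
  methmedint:::new_model_fit(coefs, vc, sigma2_e = 1, sigma2_g = 0,
                             n = 100L)
}
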