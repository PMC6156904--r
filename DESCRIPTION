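Package: methmedint
Title: Mediation and Interaction Analysis of SNP Effects Through DNA
    Methylation Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacoepigenetic mediation-interaction analysis of
    treatment-response phenotypes. Screens SNPs and CpG sites with marginal
    association models, selects proximal SNP-CpG pairs, and jointly fits a
    mediator model (change in methylation on genotype) and an outcome model
    (change in log-triglycerides on genotype, methylation change, and their
    product) to estimate the natural indirect effect with a delta-method
    standard error and to test gene-methylation interaction. Supports
    kinship-adjusted linear mixed models fitted by REML for family-based
    cohorts, a synthetic-data generator emulating the study design, and a
    simulation-based power engine for the indirect-effect test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
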