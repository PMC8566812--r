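Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("mrpipe", "developers", email = "mrpipe@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) with GWAS
    summary statistics: reading and validating per-SNP association tables,
    harmonizing exposure and outcome effects to a common effect allele
    (including strand complements, palindromic-variant policies, LD clumping
    and proxy substitution), causal estimation by Wald ratio,
    inverse-variance weighting, weighted median and MR-Egger regression,
    heterogeneity and leave-one-out sensitivity analyses, a summary-level
    simulator with known ground truth for estimator validation, and a
    config-driven multi-exposure pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
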