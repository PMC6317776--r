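Package: summaryMR
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-sample mendelian randomization with GWAS summary
    statistics: instrument filtering (genome-wide significance, imputation
    quality), greedy LD pruning, allele harmonization with palindromic-variant
    handling, likelihood-based and inverse-variance-weighted causal estimation,
    pleiotropy-robust estimators (weighted median, MR-Egger with SIMEX
    measurement-error correction, MR-PRESSO residual-sum global and outlier
    tests), fixed-effect stratum meta-analysis with heterogeneity tests,
    a priori power calculation for binary outcomes, leave-one-out and
    funnel-plot diagnostics, and a synthetic summary-statistics generator
    with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
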