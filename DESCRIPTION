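Package: crcprs
Title: Weighted Polygenic Risk Score Analysis for Familial Colorectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a control-anchored weighted polygenic risk score (wPRS)
    from a variant weight panel and genotype dosages, with imputation-quality
    filtering, allele harmonization, optional winner's-curse correction of
    discovery effect sizes, and proportional rescaling for missing genotypes.
    Provides the downstream association battery used in familial/early-onset
    colorectal cancer case-control studies: covariate-adjusted logistic
    odds ratios per score unit, quantile-based risk stratification against a
    median reference quantile, clinical-feature contingency analysis, ROC/AUC
    and liability-scale heritability with leave-one-covariate-out contribution
    decomposition, and a liability-threshold cohort simulator with familial
    ascertainment for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    stringr,
    jsonlite,
    stats,
    utils,
    generics,
    vcfR
Suggests:
    yaml,
    withr,
    testthat (>= 3.0.0),
    pROC,
    broom
Config/testthat/edition: 3
RoxygenNote: 7.3.3
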