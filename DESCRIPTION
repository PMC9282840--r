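Package: longprs
Title: Polygenic Risk Score Trade-Off Analysis Between Complex Diseases
    and Longevity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying genetic trade-offs between complex diseases
    and human longevity with polygenic risk scores (PRSs). Implements GWAS
    summary-statistic harmonization (allele matching, strand flips,
    exclusion of ambiguous palindromic variants), greedy LD clumping and
    p-value thresholding, per-individual PRS scoring, logistic association
    scans with Nagelkerke pseudo-R2 and multiple-testing control,
    annotation-set and p-value-bin stratified PRSs, region masking with
    D-prime confidence-interval LD-block detection, effect-direction
    dissection of pleiotropic variants, and a repeated cross-validated
    multi-PRS longevity classifier. A synthetic-cohort generator produces
    LD-blocked genotypes, liability-threshold case/control phenotypes and
    summary statistics with planted bidirectional effects so the whole
    pipeline is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    pROC,
    glmnet,
    e1071,
    class,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
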