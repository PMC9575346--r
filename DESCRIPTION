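Package: jdinac
Title: Differential Gene Interaction Networks from SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers case-control differential gene interaction networks from
    SNP genotypes. Genotypes are aggregated into per-gene risk scores, and a
    joint density-based nonparametric differential interaction network
    analysis (JDINAC) is performed: group-conditional bivariate kernel
    densities yield log density-ratio features that enter an L1-penalized
    logistic regression with covariate adjustment, repeated over random
    sample splits to produce edge importance scores, a thresholded network
    and hub genes. Also provides per-SNP covariate-adjusted logistic
    association (odds ratios with Wald intervals), split-sample validation
    of single edges, contingency-table chi-square reports for cohort
    demographics, and a Gaussian-copula cohort simulator with planted
    differential edges for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    igraph,
    vcfR,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
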