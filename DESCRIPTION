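Package: greyherit
Title: Quantitative Genetics of Greying, Melanoma, and Skin Pigmentation
    Traits in Grey Horses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pedigree-based animal-model analysis of the four pigmentation
    traits of Grey horses (melanoma grade, grey level, vitiligo grade and
    speckling grade): average-information REML estimation of univariate and
    bivariate repeated-records animal models with major-locus (STX17, ASIP)
    fixed effects, decomposition of phenotypic variance into polygenic,
    single-locus, permanent-environment and residual parts, and a
    three-scenario genetic-correlation analysis that attributes between-trait
    correlations to major-gene pleiotropy versus polygenic background.
    Includes Mendelian genotype deduction from coat colour and pedigree,
    and a gene-dropping simulator that emulates the structure of a
    multi-stud longitudinal study for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
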