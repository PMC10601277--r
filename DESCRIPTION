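Package: methresp
Title: DNA Methylation Signatures of Induction-Therapy Response in AML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end derivation and evaluation of DNA-methylation
    signatures predicting response to induction chemotherapy in acute
    myeloid leukemia. Implements genome-binned differential-methylation
    screening of methyl-CpG immunoprecipitation sequencing counts
    (TMM normalization, conditional-likelihood negative-binomial
    dispersion estimation, exact two-group testing, FDR control),
    multi-criteria differentially methylated region selection with
    chromosome and arm-overlap exclusions, cross-platform confirmation
    against methylation-array beta values, an in-silico EpiTYPER
    mass-spectrometry layer (bisulfite conversion, U-specific cleavage
    fragmentation, CpG-unit informativeness, missingness QC and
    k-nearest-neighbour imputation), penalized-logistic signature
    training with cross-validation, and 0.632+ bootstrap estimation of
    misclassification error and AUC. A synthetic cohort generator
    emulates all three measurement platforms with planted
    response-associated differential methylation so that every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    glmnet,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    pROC
Config/testthat/edition: 3
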