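Package: hlapanel
Title: Population-Specific HLA Imputation Panels: Training, Evaluation
    and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains attribute-bagging HLA imputation models (ensembles of
    SNP-subset classifiers with EM-estimated extended-haplotype frequency
    tables) on reference panels with clinical-grade HLA types, imputes
    two-field HLA genotypes with posterior probabilities in target cohorts,
    and quantifies the value of a population-matched reference panel:
    bootstrap error distributions, paired permutation tests, ROC/AUC on
    posterior probabilities, posterior-threshold sweeps, cross-validated
    reference selection, imputed allele-frequency validation against
    independent typing data, and logistic-regression association of imputed
    allele dosages with case-control phenotypes. Includes a synthetic-data
    generator for two related populations sharing common SNP-HLA haplotypes,
    one of which carries enriched rare haplotypes absent from the other.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
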