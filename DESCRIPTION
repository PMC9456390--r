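Package: osteopgs
Title: Polygenic Score Pipeline for Osteoporosis Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-individual polygenic scores for primary osteoporosis
    from targeted SNP panels and evaluates them against fracture, low
    bone-mineral-density, and comorbid case-control contrasts. Provides
    genotype quality control (call rate, minor allele frequency, exact
    Hardy-Weinberg test, linkage-disequilibrium pruning), a principal-component
    population-stratification check, score normalization, and a full
    evaluation battery (ROC/AUC with DeLong intervals, Youden operating point,
    decile risk stratification with Cochran-Armitage trend test, odds ratios
    per standard deviation). A seeded liability-threshold cohort simulator
    generates genotype panels and correlated fracture/BMD phenotypes so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
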