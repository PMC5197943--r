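Package: dmetsurv
Title: Genotype-Stratified Survival Screening for Pharmacogenomic SNP Matrices
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens every probe of a genotype-call matrix (such as the
    1936-probe DMET ADME panel) annotated with clinical outcomes. Patients
    are stratified by genotype at each probe, overall-survival and
    progression-free-survival curves are estimated per genotype group with
    the Kaplan-Meier product-limit estimator, groups are compared with the
    Mantel-Cox log-rank test and observed/expected hazard ratios, and probes
    are ranked by significance. Includes readers and writers for the
    clinically annotated matrix layout (tab-delimited, CSV, xlsx), a
    synthetic cohort generator with known genotype-dependent hazards for
    end-to-end validation, report export, step-curve plotting, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    readxl,
    zip
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Survival, SNP, Software, StatisticalMethod
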