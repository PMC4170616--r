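Package: gliosig
Title: DNA-Repair Prognostic Signatures and Interaction Networks for High-Grade Glioma Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds DNA-repair prognostic gene signatures from expression
    cohorts of high-grade glioma: optimal-cutpoint dichotomization of probe
    expression against overall survival with false-discovery-rate control,
    cross-cohort consensus and iterative multivariate Cox model reduction, a
    beta-weighted prognostic index with risk-group stratification and
    polynomial year-survival curves, multilayer-perceptron screening and
    pairwise gene-interaction network inference with hub detection, an
    ensemble leave-one-out cross-validated classifier with moderated-t gene
    selection, and immunohistochemistry H-score utilities. Includes a
    synthetic-cohort generator with planted survival effects, hub-driven
    expression blocks and two-class structure so the whole workflow can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    xml2,
    e1071,
    ranger,
    class,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
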