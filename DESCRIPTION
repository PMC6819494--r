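Package: thyroclass
Title: Molecular Classification of Thyroid FNA Samples from qPCR Marker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the preoperative molecular classification of thyroid
    fine-needle aspiration (FNA) samples from a small real-time PCR marker
    panel: delta-Cq normalization of 13 target miRNAs against the geometric
    mean of three reference miRNAs, HMGA2 mRNA quantification against PGK1,
    the mitochondrial-to-nuclear DNA copy ratio, somatic mutation and
    translocation rules, a molecular regrouping of follicular-pattern tumors
    into classes with and without markers of malignancy, two fixed decision
    trees for malignancy calling and tumor typing, a from-scratch C4.5-style
    decision-tree trainer with gain-ratio splits and pessimistic pruning,
    stratified cross-validation, diagnostic-accuracy statistics (sensitivity,
    PPV, NPV, ROC AUC, Mann-Whitney tests), and a seeded synthetic-cohort
    generator that emulates the per-histotype structure of a clinical FNA
    series so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
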