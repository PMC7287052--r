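Package: TIMEsig
Title: Gene-Panel Z-Score Classification of the Tumor Immune
    Microenvironment with Mutation Enrichment and Metabolic Phenotyping
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies bulk tumor transcriptomes into immune-activated,
    immune-suppressed and immune-absent tumor immune microenvironment (TIME)
    subtypes using directional gene-panel rules on per-gene expression
    z-scores; screens non-synonymous mutations for subtype enrichment with
    exact contingency tests (Fisher 2x2 and Freeman-Halton 2x3); scores
    glycolysis and oxidative-phosphorylation transcriptional programs within
    expression strata; compares survival between subtypes with Kaplan-Meier
    curves and the Gehan-Wilcoxon test; and analyses paired control/treated
    perturbation experiments. A synthetic multi-omic cohort generator with
    planted ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcriptomics, Classification, SomaticMutation, Survival,
    ImmunoOncology
RoxygenNote: 7.3.3
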