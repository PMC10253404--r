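Package: probeCapture
Title: Chemoproteomic Probe-Capture Analysis for Flavonoid Enzyme Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for affinity-based chemoproteomic capture
    experiments with label-free quantification. Aggregates peptide-level
    intensity reports into normalized protein abundance matrices, applies
    fold-change/ANOVA capture-significance tiers against probe-less negative
    controls, compares captured-protein sets across probes and capture
    methods, computes probe-vs-probe selectivity volcano statistics, screens
    candidates by functional annotation with GO-term enrichment, and
    shortlists candidate flavonoid enzymes by local sequence similarity to
    known flavonol hydroxylases. Includes a ground-truthed synthetic-data
    generator emulating triplicate capture designs with left-censored
    missingness for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
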