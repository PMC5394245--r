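Package: mexTF
Title: Mutually Exclusive Master Transcription Factor Discovery from
    Expression Aberrations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies master transcription factors (TFs) that dysregulate
    a shared module of target genes (for example microRNAs) in mutually
    exclusive subsets of tumour samples, from paired continuous expression
    profiles. Continuous expression is discretized into binary aberration
    calls with per-gene Gaussian mixture models (z-score outliers relative
    to the normal cluster, direction chosen by metastatic-sample
    enrichment); TF-target regulation is inferred with modified one-sided
    Fisher's exact tests on relaxed TF-based target cutoffs under
    Benjamini-Hochberg control; the candidate graph is pruned to a minimal
    driver set with a minimum description length (MDL) objective; and
    master-TF status, shared-target overlap, mutual exclusivity and
    bimodality-index screening statistics are reported. A synthetic-cohort
    generator with planted mutually exclusive drivers supports end-to-end
    validation with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    mclust,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: GeneRegulation, NetworkInference, Transcription, Software
RoxygenNote: 7.3.3
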