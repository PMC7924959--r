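Package: sumoscape
Title: Site-Level Analysis of SUMO-Modified Proteomes from Label-Free
    Quantification Time Courses
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of di-glycine remnant SUMO-proteomics
    experiments quantified by label-free quantification (LFQ) across a
    time course. Reads MaxQuant-style modification-site and protein-group
    tables, filters decoy and contaminant matches, classifies conjugation
    sites into SUMO consensus-motif categories, quantifies site clustering
    along proteins (distance-resolved SUMOylation probability curves),
    computes fold-enrichment of sites across protein structural contexts
    (intrinsic disorder, solvent accessibility, coiled coils,
    transmembrane segments), and runs the quantitative pipeline of
    replicate averaging, log2 transformation, column-wise downshifted
    normal imputation, row z-scoring and hierarchical clustering by
    one-minus-Pearson distance. A synthetic-data generator emulates the
    statistical structure of such experiments (planted motifs, disorder
    enrichment, site clusters, temporal profile classes,
    intensity-dependent missingness) for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
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
    mclust,
    withr
biocViews: Proteomics, PostTranslationalModification, MassSpectrometry,
    TimeCourse, Clustering, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
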