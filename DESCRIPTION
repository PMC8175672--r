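Package: sRNArank
Title: Prediction of Bacterial Small RNAs from RIL-Seq Interaction Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ranks RNAs by their probability of being Hfq-dependent small
    regulatory RNAs (sRNAs) using quantitative features derived from RIL-seq
    chimeric-fragment interaction data. Aggregates statistically significant
    chimera (S-chimera) tables into per-RNA interaction profiles, computes
    first-layer features (normalized chimera and interaction counts, the
    Second-In-Chimera score, terminator U-tract length) and second-layer
    features summarizing each RNA's interaction partners, screens features by
    Mann-Whitney tests with Bonferroni correction and correlation clustering,
    and scores every RNA with repeated stratified-split L2-regularized
    logistic regression. Includes feature-contribution decomposition, ROC and
    precision-recall evaluation with relabeling analysis, PCA projection,
    target-hub flagging, biogenesis evidence annotation (transcription start
    sites, RNase E cleavage sites, CLASH overlap), and a synthetic RIL-seq
    data generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    Biostrings,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    S4Vectors,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
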