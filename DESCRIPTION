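Package: sigreverse
Title: Transcriptional Signature Reversal Analysis for Drug Repurposing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Connectivity-mapping toolkit for transcription-based drug
    repurposing. Builds disease expression signatures from case/control
    contrasts (bounded scaled-fold statistics with significance filters) and
    from ordinal disease-stage regressions, converts drug perturbation
    experiments into filtered gene-level profiles (CMAP-style rank transforms
    with replicate aggregation and probe collapse, plate-normalised fold and
    Z-score treatment profiles), scores drugs for signature reversal by sense
    concordance with exact Poisson-binomial enrichment, assesses rank
    enrichment with a Kolmogorov-Smirnov running-sum statistic and a
    Monte-Carlo null, and summarises hit sets by sum-sense consensus, UPGMA
    clustering and gene-set over-representation. Includes a synthetic-data
    generator that plants known disease signatures and reverser drugs so the
    whole pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: GeneExpression, DifferentialExpression, Pharmacogenomics,
    Clustering, Software
RoxygenNote: 7.3.3
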