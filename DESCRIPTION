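Package: RepeatInstability
Title: Quantification and Expression-Based Modeling of Tissue-Specific
    Trinucleotide Repeat Somatic Instability
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying somatic instability of trinucleotide
    (CAG) repeats from capillary-electrophoresis fragment-analysis peak
    traces using a relative peak-height threshold, including the
    instability index and its companion metrics (expansion and contraction
    indices, peak counts, peak composition, main-allele shift) and a
    small-pool PCR instability index from single-molecule repeat-length
    distributions.  Also provides a correlation-ranked forward-selection
    partial least squares regression model that predicts tissue instability
    from gene expression with honest leave-one-tissue-out cross-validation,
    continuous-phenotype gene set enrichment analysis with a
    phenotype-permutation null, and a fully ground-truthed synthetic-data
    generator (somatic repeat-length distributions, PCR stutter and
    shorter-allele amplification bias, planted expression signatures) for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, GeneExpression, Regression, GeneSetEnrichment,
    Sequencing
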