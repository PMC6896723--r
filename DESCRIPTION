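Package: ffpeReliability
Title: Reliability of FFPE RNA-Seq Gene Expression Across RNA Extraction Kits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the reliability of gene expression measured
    by RNA sequencing from formalin-fixed paraffin-embedded (FFPE) tumor
    tissue against matched fresh-frozen (FF) samples, across RNA extraction
    kits, in a replicated paired design. Implements reference-gene panel
    normalization, per-gene agreement via Lin's concordance correlation
    coefficient with its correlation/bias decomposition, REML estimation of
    a gene-level mixed model decomposing kit bias, across-tumor bias
    variance and replicate noise, paired two-factor differential analysis
    with Benjamini-Hochberg correction, two-gene-set signature scoring with
    an expression-matched random-signature null, Bland-Altman agreement, and
    a synthetic-data generator that emulates the replicated FF/FFPE study
    design with full ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, QualityControl, Normalization
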