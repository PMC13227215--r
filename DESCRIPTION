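Package: beemarker
Title: Nutritranscriptomic Differential Expression and Biomarker Discovery
    for Honey Bee Diet Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a cage-level honey bee
    nutritranscriptomics analysis chain: low-count filtering,
    median-of-ratios normalization and a parametric variance-stabilizing
    transformation; precision-weighted moderated differential expression
    with manual contrasts and colony blocking; leading-logFC
    multidimensional scaling and correlation-based clustering;
    random-forest recursive feature elimination with out-of-bag model
    selection and Pearson-correlation biomarker triage; linear SVM-RFE
    genotype classification scored by external cross-validation; and DEG
    set algebra with lncRNA biotype enrichment. Ships a negative-binomial
    count simulator that emulates the two-stock, four-diet, multi-colony
    cage design with planted diet, stock and body-weight expression
    programs so every stage can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    jsonlite,
    ranger,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    limma,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'diffexpr.R'
    'dimred.R'
    'fixtures.R'
    'preprocess.R'
    'rf.R'
    'setops.R'
    'simulate.R'
    'svm.R'
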