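Package: ReceptorSig
Title: Multi-Gene Signatures for Hormone Receptor and ERBB2 Status from
    Breast Tumor Expression Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives and applies multi-probe-set gene expression signatures
    predictive of estrogen receptor (ER), progesterone receptor (PR) and
    ERBB2 (HER2) clinical status in breast tumor expression profiles.
    Probes are ranked by Spearman correlation with the binary clinical
    status, candidate signatures are swept over a grid of correlation
    cutoffs, per-sample status is called by 2-means clustering in signature
    space, and the cutoff maximizing sensitivity plus specificity is
    retained. A single-probe-set two-component Gaussian mixture (EM)
    baseline, a full diagnostic-test evaluation battery (confusion matrix,
    accuracy, sensitivity, specificity, PPV, NPV, Fisher's exact test,
    cross-dataset t-based confidence intervals, method-comparison t-tests),
    and a synthetic-data generator with planted ground truth are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
biocViews: GeneExpression, Classification, Microarray, BreastCancer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'align.R'
    'correlation.R'
    'evaluation.R'
    'io.R'
    'mixture.R'
    'pipeline.R'
    'predictor.R'
    'sweep.R'
    'synthetic.R'
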