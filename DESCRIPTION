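Package: gfrn
Title: Growth Factor Receptor Network Pathway Signatures and Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gene-expression signatures of growth factor receptor
    network (GFRN) pathway activation from overexpression-versus-control
    training data, estimates scaled per-sample pathway activity in tumor and
    cell-line cohorts after reference-batch harmonization, optimizes
    signature gene-list lengths against protein-array correlations,
    classifies samples into survival/growth phenotypes and four k-means
    subgroups, attributes principal-component variance to subgrouping
    schemes via nested linear models, and links phenotypes to drug response
    through two-parameter logistic dose-response fitting and correlation
    analysis. Includes a synthetic-data generator that emulates the full
    study design so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    pROC,
    mclust,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
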