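Package: mtxresponse
Title: Classifying Methotrexate Nonresponse from Paired Whole-Blood
    Expression Profiles in Rheumatoid Arthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying early transcriptomic classifiers of
    methotrexate nonresponse in rheumatoid arthritis from paired
    pretreatment and 4-week whole-blood expression profiles.  Implements
    delta-expression (log2-ratio) feature construction with leakage-safe
    nested cross-validation over regularized logistic regression, random
    forest and pathway-aggregated model families; weighted gene
    coexpression network analysis (soft-threshold selection by the
    scale-free topology criterion, topological overlap, dynamic tree
    cutting, consensus and group-specific module detection, hub gene
    ranking); hypergeometric over-representation of module gene lists;
    and a synthetic cohort generator with planted coexpression modules,
    planted longitudinal response signal, and clinical covariates with
    EULAR response labels derived from simulated DAS28-CRP trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    randomForest,
    limma,
    fgsea,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC
Config/testthat/edition: 3
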