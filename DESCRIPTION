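Package: rgstage
Title: Radiogenomic Staging of Bladder Cancer from MR Radiomics and RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for binary intra- versus extra-vesical
    staging of muscle-invasive bladder cancer that integrates 3D radiomic
    texture and shape features extracted from masked MR tumor volumes with
    genomic predictors derived from RNA-seq counts (negative-binomial Wald
    differential expression and single-sample gene set enrichment scores).
    Includes mask-constrained extraction of first-order, GLCM, GLRLM, GLSZM,
    GLDM, NGTDM and shape features over a bin/kernel/angle parameter sweep;
    Student t and Bhattacharyya-coefficient feature screening with redundancy
    reduction; recursive feature elimination with a per-category feature cap
    across five classifier families; and a seeded synthetic radiogenomic
    cohort generator that provides a ground-truthed test surface for every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    e1071,
    class,
    rpart,
    igraph
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
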