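Package: parafuse
Title: Parallel Independent Component Analysis for Imaging Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint decomposition of a SNP dosage matrix and a voxel-wise
    gray-matter volume matrix into coupled independent components
    (parallel ICA), with minimum-description-length model-order selection,
    EIGENSTRAT-style population-stratification correction, leave-N-out
    component stability checks, loading-coefficient association testing,
    VEGAS-style Monte-Carlo gene-based statistics, and hypergeometric
    pathway enrichment.  Includes a linked synthetic-data generator with
    known ground truth (sparse latent components, cross-modality loading
    correlation, group effects, LD blocks, two-subpopulation structure)
    so the whole chain can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    RNifti,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    car,
    MASS
Config/testthat/edition: 3
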