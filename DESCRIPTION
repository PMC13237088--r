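Package: lcrbench
Title: Benchmarking and Complexity-Space Analysis of Protein Low-Complexity Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tool-agnostic framework for characterising protein low-complexity
    regions (LCRs) in a two-axis complexity space defined by mutational distance
    to a perfect repeat and compositional dominance. Reads protein FASTA and
    BED-like region tables, builds an operational reference annotation by
    sliding-window scanning, computes residue-level multi-method consensus and
    Jaccard similarity, evaluates predictions with stratified residue-level
    TPR/FPR, and estimates probabilistic low-complexity boundaries with a
    binned smoothed-frequency estimator, ROC/Youden thresholding and a
    penalised-spline logistic surface. Includes a deterministic synthetic-data
    generator with planted homorepeats, imperfect tandem repeats and simulated
    pseudo-method predictions so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    mgcv,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
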