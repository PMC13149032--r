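Package: mfispat
Title: Spatial Niche and Invasiveness Analysis for Maternal-Fetal Interface Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing submicrometre spatial transcriptomic sections of
    the human maternal-fetal interface: signed distance fields to the interface
    polyline and to spiral-artery walls, distance-binned cell-type composition
    profiles, randomized-region tests for perivascular trophoblast enrichment,
    marker-quadrant classification of remodelling arterial endothelial states,
    composite differential-expression scores and bin-controlled module scores,
    an L1-penalized invasiveness score (iScore) learned from depth-window
    pseudobulks, local stromal-adjacency contrasts on invasiveness, and
    classification of signed gene-regulatory edges into lineage toggle-switch
    categories. Includes a synthetic tissue generator with planted ground truth
    so every stage is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
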