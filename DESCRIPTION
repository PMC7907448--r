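Package: flowtraj
Title: Eigengene Trajectory Analysis of Endothelial Flow Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting transcriptome trajectories from time-series
    RNA-seq of endothelial cells under contrasting shear-stress regimes.
    Implements log2-CPM normalization, mean-centered singular value
    decomposition with per-condition component-score trajectories, eigengene
    ranking by absolute loading, projection of external expression data into a
    fitted component space, nearest-neighbour mutual-information ranking of
    genes against a discrete condition label, a sign-concordance screen for
    candidate regulators across stimulus contrasts, and a negative-binomial
    time-course simulator with planted expression programs for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
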