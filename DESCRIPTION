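Package: ggtqa
Title: Gated Graph Transformer Quality Assessment for Protein Complex Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-model estimation of protein complex structure quality.
    Parses multi-chain PDB models into per-residue records, builds a k-nearest-
    neighbour residue graph with geometric and biophysical node and edge
    features, and scores it with a gated graph transformer whose node and edge
    information gates modulate message passing.  Dual read-out heads predict a
    DockQ-like quality score in [0,1] and a four-class CAPRI-style quality
    category.  Includes DockQ label construction from fnat/iRMSD/LRMSD
    components, desk-scale multi-task training with hand-verified gradients,
    ranking-loss and Top-N hit-rate evaluation of decoy rankings, and a
    synthetic fixture generator producing toy complexes and graded decoy pools
    with computable ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
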