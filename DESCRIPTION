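Package: xlinkval
Title: Structural Validation and Homo-Multimer Discovery for Cross-Linking
    Mass Spectrometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated structural analysis and validation of cross-linking mass
    spectrometry (XL-MS) experiments. Normalizes cross-link tables to full-protein
    coordinates by Smith-Waterman alignment of peptides against their protein
    sequences, detects homo-multimer evidence from overlapping cross-linked
    peptides, selects experimental or predicted structures from a local library by
    sequence identity, coverage and resolution, computes Euclidean and
    protein-volume-avoiding topological distances between linked residues on a
    voxel occupancy grid, and reclassifies out-of-range intra-protein links as
    candidate homo-multimeric inter-protein links by enumerating chain-pair
    permutations. Includes a synthetic fixture generator with known ground truth,
    a results writer, PyMOL viewer-script generation, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
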