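Package: SAMotions
Title: Structural-Alphabet Analysis of Local Motions in Protein
    Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Encodes protein conformational ensembles (e.g. molecular
    dynamics trajectories) into strings over a structural alphabet of
    canonical four-residue C-alpha fragments via least-squares rigid
    superposition, and analyzes the resulting string alignment: per-position
    Shannon entropy and fragment profiles, transition matrices, mutual
    information between fragment positions with permutation-based
    normalization and significance, correlation networks with eigenvector
    centrality and communication-pathway extraction (GML export), and
    correlation of local motions with a time-dependent functional index.
    Includes a synthetic-ensemble generator with planted couplings for
    ground-truth validation, and command-line style drivers for the
    encode/analyze/synthesize workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
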