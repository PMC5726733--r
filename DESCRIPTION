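Package: pathnull
Title: Null-Model Benchmarks for Contiguous Residue Pathways in Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the statistical significance of contiguous residue
    pathways between allosteric and active sites in protein structures.
    Builds residue contact graphs from minimum inter-atomic distance
    matrices, draws random fixed-fraction residue selections with the two
    site residues held fixed, decides path existence in the induced
    subgraph with depth-first and A* searches, and reports Monte Carlo
    pathway success rates with trial-level convergence. Includes an
    exhaustive-enumeration oracle for small systems, cutoff-distance
    sweeps with asymmetric five-parameter logistic fits, and a generator
    of protein-like synthetic bead structures (compact globules and
    multidomain chains with thin linkers) so the whole pipeline is
    testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
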