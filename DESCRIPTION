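Package: squirrel
Title: Semi-Directed Level-1 Phylogenetic Network Reconstruction from Quarnets
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs binary triangle-free semi-directed level-1
    phylogenetic networks from dense sets of weighted four-leaf networks
    (tf-quarnets) with the Squirrel algorithm: candidate blobtrees are built
    from the quartet trees in the input, high-degree vertices are expanded
    into cycles by solving travelling-salesman instances on quarnet-derived
    distances, and the candidate with the highest weighted tf-quarnet
    consistency score is returned.  Includes the delta-heuristic that infers
    dense weighted tf-quarnet sets directly from multiple sequence
    alignments, eNewick input/output, outgroup rooting, and simulation
    machinery (random level-1 network generation, quarnet perturbation,
    Kimura two-parameter sequence simulation along displayed trees) for
    validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    data.table,
    igraph,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
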