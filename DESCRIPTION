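Package: pocketome
Title: Comparative Analysis of Predicted Protein Binding-Pocket Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-species analysis of predicted small-molecule
    binding pockets on modelled protein structures. Filters pocket
    predictions by structure-confidence criteria (pLDDT, predicted aligned
    error, ligandability probability), computes physicochemical pocket
    descriptors (hydropathy, aromaticity, net charge, relative
    solvent-accessible surface area), quantifies ligand-class enrichment
    among recovered annotated binding sites with Fisher exact tests and
    Benjamini-Yekutieli correction, clusters within-species pocket
    similarity graphs with Leiden community detection and degree-preserving
    null models, estimates the power-law exponent linking fold-cluster
    counts to unique-pocket counts across species, and maps label entropy
    over 2D projections of pocket embedding vectors. A synthetic-data
    module generates every pipeline input with controllable statistical
    structure for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
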