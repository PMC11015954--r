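Package: multidta
Title: Multigranular Protein-Ligand Binding Affinity and Binding Region
    Prediction
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint prediction of continuous protein-ligand binding
    affinities (pKd scale) and binding regions on the protein sequence
    from SMILES strings and amino-acid sequences. Ligands are encoded at
    three granularities (graph attention network over the molecular
    graph, residual 1-D convolutions over the character sequence, and a
    transformer over frequent sub-structure tokens); proteins are encoded
    by a gated-convolution variational autoencoder over overlapping
    3-mers. A bilinear attention interaction module fuses the
    granularities and a response-vector head localizes the binding
    region. Includes a seeded synthetic-data generator with planted
    binding motifs, evaluation metrics (concordance index, rm2, AUPR,
    region accuracy), cold-split protocols, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
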