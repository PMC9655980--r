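Package: qsarkit
Title: Molecule Curation, Descriptors, Fingerprints and Nearest-Neighbour
    QSAR Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end workflow for binary QSAR classification built
    around tidy molecule tables: reading and writing SMILES and MDL SDF
    files, structure checking and rule-based standardization (including
    reaction-SMARTS custom rules), duplicate and Bemis-Murcko scaffold
    analysis, a small catalogue of interpretable 0D-2D molecular
    descriptors (mean atomic polarizability, path counts, SHannon Entropy
    Descriptors over pharmacophore points, frequency atom pairs, topological
    polar surface area, Moriguchi logP), MACCS-166 and extended-connectivity
    fingerprints, k-nearest-neighbour and majority-vote consensus
    classifiers with genetic-algorithm feature selection, cross-validation,
    Y-randomization, leverage and distance applicability domains, and a
    portable JSON project format for applying fitted models to new
    molecules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ChemmineR,
    class,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
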