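Package: mcphd
Title: Maximum Common Property Molecular Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based 3D molecular similarity by the maximum common
    property approach. Computes a per-atom electrotopographic state index
    (an E-state variant whose perturbation term uses 3D Euclidean rather
    than graph distances), reduces molecules to descriptor centers (ring
    systems, branching clusters, heteroatom groups and terminal groups)
    carrying summed index values and centers of mass, matches descriptor
    centers between two molecules by property similarity and
    Canberra-consistent geometry, and scores the matched fragments with a
    modified Tanimoto coefficient. Includes the evaluation layer used in
    ligand-based virtual screening studies: potency-similarity (TcIC50),
    threshold screening tables, Pearson correlations and Mann-Whitney rank
    tests, plus deterministic 3D fixture generators and packaged reference
    tables so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
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
    withr,
    optparse
Config/testthat/edition: 3
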