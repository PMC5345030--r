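Package: rnadenature
Title: Coarse-Grained Denaturation and Restrained Folding of RNA Phosphate Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coarse-grained simulator for exploring how far an RNA fold can
    drift under random perturbation of its secondary-structure elements, and
    how strongly sparse predicted tertiary contacts restrict that drift.
    Represents each nucleotide by its phosphate atom, treats ladders of three
    or more consecutive base pairs as rigid helical elements, and refines
    virtual bonds, local geometry and one-sided pair restraints with fixed
    per-cycle steps. Includes readers and writers for phosphate-trace PDB
    files, dot-bracket strings, scored contact tables and SimRNA-dialect
    restraint files; restraint ranking, truncation and classification against
    a native structure; superposition RMSD, distance-matrix RMSD and ensemble
    maximum-distance metrics; denaturation-profile, perturbation-sweep and
    circular-start folding protocols; and a generator of ideal-geometry
    synthetic fixtures (helix, stem-loop, Y, cruciform) with planted contact
    predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    bio3d,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
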