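Package: specmap
Title: Phenotype-Separating Residue Analysis and Docking Workup for
    Species-Specific Receptor Agonists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for explaining why an agonist activates a receptor in some
    species but not others. Finds alignment columns in an accessory-protein
    ortholog alignment whose amino-acid identity sets are disjoint between
    responder and non-responder species, places those residues in structural
    context (ligand pocket, dimerization interface, or distal surface) on
    receptor complexes via Kabsch superposition and distance rules, builds
    docking search boxes and flexible-residue shells, clusters scored docking
    poses into binding modes with contact maps and inter-mode score gaps, and
    summarises dose-response and cytokine data (trapezoid and cubic-spline
    AUC, four-parameter-logistic pEC50, percent difference from a reference
    agonist with Fieller or bootstrap confidence intervals). A synthetic-data
    module generates every input with planted ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
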