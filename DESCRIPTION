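Package: csppocket
Title: Chemical Shift Perturbation Mapping of Protein-RNA Binding Pockets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of protein-ligand binding interfaces from NMR chemical
    shift perturbation (CSP) titrations and fluorescence binding assays.
    Reads assigned backbone shift tables (NMR-STAR subset or TSV), Sparky
    peak lists, PDB coordinates and FASTA sequences; tracks HSQC peaks
    across a ligand titration; computes per-residue weighted CSPs and the
    mean-plus-k-standard-deviations significance threshold; classifies
    slow versus fast exchange and assesses binding stoichiometry from the
    CSP plateau; compares homolog binding pockets by global sequence
    alignment, residue mapping and Kabsch superposition; and fits
    saturation and competition binding isotherms with the exact
    ligand-depletion (quadratic) equilibrium model. A synthetic-data
    module generates titrations, binding curves and structure pairs with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
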