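Package: qtykit
Title: Design and Characterization of Water-Soluble QTY Analogs of
    Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Applies the QTY amino-acid substitution code (L->Q, I->T,
    V->T, F->Y) inside annotated transmembrane segments to design
    water-soluble analogs of integral membrane proteins, and provides the
    characterization pipeline used to validate such designs:
    sequence-variation statistics and alignment rendering, molecular
    weight and Expasy-style isoelectric point, Kyte-Doolittle hydropathy,
    Kabsch rigid-body superposition with optional outlier-rejection
    cycles, Shrake-Rupley solvent-accessible surface area with
    hydrophobic-surface fractions, and ligand binding-site contact and
    conservation analysis. Includes a synthetic-fixture generator
    (sequences plus ideal-helix bundles) so the full pipeline runs and
    tests without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
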