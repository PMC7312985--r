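Package: proteogel
Title: Proteoform Annotation from 2DE-Coupled Shotgun Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sample-customized combinatorial proteoform libraries from
    transcript and variant tables, performs in-silico tryptic digestion and
    peptide-level proteoform/protein-group inference from per-gel-cell peptide
    identifications, and annotates proteoforms by comparing theoretical
    isoelectric point and molecular weight against calibrated two-dimensional
    electrophoresis (2DE) gel-cell coordinates. Discordant localizations are
    classified by a shift taxonomy covering proteolysis, complex or oligomer
    formation, acidic and basic post-translational modification shifts, and
    proline-rich migration retardation. Includes a ground-truthed synthetic
    experiment generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
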