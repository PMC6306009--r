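Package: cutinseq
Title: De Novo Sequencing of Cutin Oligomers from Tandem Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for reading the acyl-chain sequence of cutin, the polyester
    matrix of the plant cuticle. Implements exact monoisotopic mass arithmetic
    for oxygenated fatty-acid monomers, a built-in apple-cutin monomer catalog
    with a parseable shorthand and symbolic nomenclature, decomposition of
    oligomer precursor masses into monomer multisets, prediction of
    ester-cleavage and chain-cleavage MS/MS fragments, inference of monomer
    order from daughter ions, overlap-based assembly of subfragments,
    interpretation of hydroxyl/carboxyl derivatization labels with a
    delta-method log-ratio standard error, and a seeded polymer, digestion and
    spectrum simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
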