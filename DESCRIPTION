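Package: mblogic
Title: Molecular Beacon DNA Logic Circuit Simulation and Strand Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates enzyme-free DNA logic circuits built on a single
    molecular beacon platform. Competing hybridizations are resolved as a
    minimum-free-energy matching under a nearest-neighbor duplex model with
    mismatch penalties, split G-quadruplex reporters are detected on unpaired
    overhangs, and dual fluorescence channels (beacon opening and
    G-quadruplex/NMM) are decoded at a fixed threshold into half-adder,
    half-subtractor, full-adder, full-subtractor and digital-comparator truth
    tables. A seeded constraint-based designer generates strand sets realizing
    each circuit, together with a design checker, fixture generator and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
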