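Package: cladeassay
Title: Design and Evaluation of Clade-Specific SSU rRNA PCR and qPCR Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building and evaluating clade-specific small-subunit
    rRNA gene assays from grouped sequence alignments: degenerate primer
    discovery, IUPAC-aware primer-template mismatch profiling, in-silico PCR
    with semi-nested clone screening, restriction-digest (RFLP) typing,
    Kimura two-parameter distances with furthest-neighbour OTU clustering,
    and absolute quantitation from qPCR dilution-series standard curves.
    Includes seeded generators for synthetic sequence families, clone
    libraries and dilution series with known ground truth.
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
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    tools,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
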