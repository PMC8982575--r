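Package: mirab
Title: Design, Cloning Simulation and Multicolor Readout for miR-AB shRNAmirs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico companion to the miR-AB shRNAmir cloning system.
    Converts 97-nt shRNAmir sequences into the 75/67-nt annealed-oligo pair
    with BamHI/ApaI-compatible sticky ends, simulates restriction digestion,
    annealing and ligation of the final construct, verifies simulated colony
    sequencing reads, removes forbidden restriction sites from protein-coding
    sequences by synonymous recoding, plans fluorescent-reporter panels
    against instrument laser/filter channels, and demultiplexes multicolor
    barcode populations from flow-cytometry event tables with per-population
    knockdown quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    igraph,
    Biostrings,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
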