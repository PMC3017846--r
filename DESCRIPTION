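Package: mircane
Title: Homology-Based Discovery of Plant miRNA Precursors and Their Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines expressed sequence tag (EST) and transcript collections for
    microRNA precursors by homology to known mature miRNAs. Implements a
    mismatch-tolerant scan for mature-miRNA matches, extraction of candidate
    precursor windows, a base-pair-weighted stem-loop folding model with
    parsers for externally computed secondary structures, validation of
    candidate hairpins against nine structural criteria including the minimal
    free energy index (MFEI), redundancy collapsing of near-identical loci,
    and a block-filtered, point-scored miRNA target predictor with G:U wobble
    and bulge penalties. Ships a synthetic-data generator that builds EST-like
    databases with embedded ground-truth precursors, decoys and planted target
    sites so the whole pipeline can be exercised end to end.
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
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
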