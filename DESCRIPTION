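Package: mtfscan
Title: Genome-Wide Identification of Membrane-Bound Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies membrane-bound transcription factors (MTFs) in
    protein sequence collections. Provides a built-in hydrophobicity-profile
    transmembrane (TM) predictor with positive-inside orientation, adapters
    for external topology predictor output (TMHMM-style reports, posterior
    probability tracks, generic topology strings), an agreement-based
    consensus over multiple predictors, a posterior-filtered TMHMM branch
    merged by union into a final MTF call set, TM-count and terminal-location
    classification, family-by-species tabulations, and a screen for
    alternative-splicing isoforms that retain the transcription-factor
    domain while losing all TM segments. A deterministic synthetic proteome
    generator with planted TM helices supports end-to-end validation without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
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
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
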