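Package: phagerflp
Title: In-Silico RFLP Typing of Bacteriophage Genomes and Phage Biocontrol Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to type bacteriophage genomes by virtual restriction digestion
    (HindIII by default), simulated agarose-gel separation with ladder-calibrated
    size inference, tolerance-based band matching with Dice (Nei-Li) band-sharing
    similarity, and UPGMA dendrogram construction with Newick export. Also provides
    the quantitative arithmetic used in phage biocontrol studies of tyramine-producing
    Enterococcus faecalis in dairy matrices: MOI dosing, percent reduction, tyramine
    unit conversion, host-range summaries, qPCR standard-curve quantification and
    pooled two-sample t-tests. A synthetic-data module generates phage-like genome
    panels evolved on a known tree, size ladders and replicated challenge counts so
    the whole pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    Biostrings
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
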