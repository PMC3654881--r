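Package: wtr
Title: Tandem Repeat Discovery in Weighted (Position-Probability) Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Locates all tandem repeats in a weighted biological sequence, i.e. a
    sequence in which each position carries a probability distribution over the
    alphabet (a position probability matrix viewed as a string). Factors are kept
    only where their cumulative occurrence probability meets a threshold 1/k, and
    repeats of every period up to half the sequence length are found by iterative
    refinement of equivalence classes of occurrence positions. Includes readers and
    writers for a per-position character:probability text format, conversion of
    multiple sequence alignments to weighted sequences by column frequencies, a
    synthetic-sequence generator with repeat planting, an independent brute-force
    reference implementation, ggplot2 visualisations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
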