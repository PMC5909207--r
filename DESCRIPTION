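Package: sovscore
Title: Segment Overlap Scores for Segmented State Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Segment-based similarity scores for pairs of equal-length state
    sequences such as protein secondary-structure strings (H/E/C or
    eight-state) or topologically associating domain (TAD) body/boundary
    strings. Implements per-position Q-k accuracy, the normalized 1999
    segment overlap score (SOV'99), and the refined segment overlap score
    (SOV_refine) whose boundary allowance is apportioned from a
    reference-wide budget so that each additional correctly assigned
    position earns an increasing reward. Includes a sliding-window mode
    for unequal-length sequences, conversion of interval lists to state
    strings for TAD comparisons, a seeded generator of perturbed
    segmentations for property testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
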