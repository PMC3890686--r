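Package: barcodegap
Title: DNA Barcode Gap Assessment and Threshold-Based Species Delimitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for distance-based DNA barcoding analysis of aligned COI
    matrices: Kimura 2-parameter distances with pairwise deletion, barcode-gap
    assessment (intra- versus interspecific distance partitions, Wilcoxon
    rank-sum test, per-specimen gap table), data-driven threshold selection by
    local minima of the pairwise-distance density, leave-one-out specimen
    identification under the best-close-match, near-neighbour and fixed
    1%-threshold criteria, single-linkage MOTU delimitation with
    morphospecies-congruence reporting, and a K80 sequence simulator that
    generates COI-like datasets with known species structure and injectable
    label errors for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
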