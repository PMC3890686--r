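#!/usr/bin/env Rscript
# Stage 4: data-driven identification threshold.
# Estimates the density of all pairwise distances and takes the first
# local minimum -- the dip between the intra- and interspecific modes --
# as the threshold for identification and MOTU delimitation.

suppressPackageStartupMessages(library(barcodegap))

dm <- read_distance_matrix("results/k2p_distances.tsv")
thr <- optimise_threshold(dm)

jsonlite::write_json(list(bandwidth = thr$bandwidth, minima = thr$minima,
                          selected = thr$selected,
                          selection_rule = thr$selection_rule),
                     "results/threshold.json", auto_unbox = TRUE, digits = NA,
                     pretty = TRUE)
write.table(data.frame(distance = thr$curve$grid, density = thr$curve$density),
            "results/density_curve.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

if (is.na(thr$selected)) {
  message("no local density minimum; downstream stages fall back to 1%")
} else {
  message(sprintf("selected threshold d = %.4f (bandwidth %.4g, %d minima)",
                  thr$selected, thr$bandwidth, length(thr$minima)))
}
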