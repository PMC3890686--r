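#!/usr/bin/env Rscript
# Stage 2: pairwise K2P distances with pairwise deletion.
# Reads the aligned FASTA and metadata written by 01_simulate.R, computes
# the full 56 x 56 Kimura 2-parameter matrix and stores it as TSV.

suppressPackageStartupMessages(library(barcodegap))

ds <- build_dataset(read_alignment("results/data/alignment.fasta"),
                    read_metadata("results/data/metadata.tsv"))
dm <- k2p_matrix(ds)
write_distance_matrix(dm, "results/k2p_distances.tsv")

v <- pairwise_values(dm)
message(sprintf("%d pairwise distances; range %.3f-%.3f",
                length(v), min(v), max(v)))
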