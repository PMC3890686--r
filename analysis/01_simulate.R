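#!/usr/bin/env Rscript
# Stage 1: generate the study-condition dataset.
#
# Five species sampled 9/12/4/11/20 times (56 specimens), 654 aligned
# sites with AT-rich composition, shallow within-species and deep
# between-species divergence, and five injected label errors standing in
# for morphological misidentifications of weathered shells. All later
# stages read the files written here.

suppressPackageStartupMessages(library(barcodegap))

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(n_species = 5L,
                         n_per_species = c(9L, 12L, 4L, 11L, 20L),
                         seq_length = 654L,
                         base_freqs = c(A = 0.242, C = 0.211, G = 0.183, T = 0.364),
                         intra_depth = 0.002, inter_depth = 0.073,
                         n_mislabels = 5L, seed = 2013L)
sim <- simulate_dataset(cfg)

write_alignment(sim$dataset$alignment, "results/data/alignment.fasta")
write.table(sim$dataset$metadata, "results/data/metadata.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(specimen_id = names(sim$true_species),
                       true_species = unname(sim$true_species)),
            "results/data/true_species.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_ground_truth(sim, "results/data/ground_truth.json")

comp <- base_composition(sim$dataset$alignment)
message(sprintf("wrote %d specimens x %d bp; composition A %.1f%% C %.1f%% G %.1f%% T %.1f%%",
                length(sim$true_species), cfg$seq_length,
                100 * comp["A"], 100 * comp["C"], 100 * comp["G"], 100 * comp["T"]))
message(sprintf("injected label errors: %s", paste(sort(sim$swapped_ids), collapse = ", ")))
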