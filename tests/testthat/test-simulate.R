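test_that("simulation is deterministic: same config, identical FASTA bytes", {
  cfg <- simulation_config(seed = 42)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(simulate_dataset(cfg)$dataset$alignment, f1)
  write_alignment(simulate_dataset(cfg)$dataset$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))

  # different seed, different data
  f3 <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(simulate_dataset(simulation_config(seed = 43))$dataset$alignment, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("the default configuration emulates the study shape", {
  sim <- simulate_dataset(simulation_config(seed = 2))
  expect_equal(length(sim$true_species), 56)
  expect_equal(as.integer(table(sim$true_species)[unique(sim$true_species)]),
               c(9L, 12L, 4L, 11L, 20L))
  expect_equal(ncol(sim$dataset$alignment), 654)
  expect_length(sim$swapped_ids, 0)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(simulation_config(n_species = 3, n_per_species = c(5, 5)),
               class = "validation_error")
  expect_error(simulation_config(base_freqs = c(A = 0.5, C = 0.5, G = 0.2, T = 0.2)),
               class = "validation_error")
  expect_error(simulation_config(intra_depth = 0.1, inter_depth = 0.05),
               class = "validation_error")
  expect_error(simulation_config(n_mislabels = 100), class = "validation_error")
  expect_error(simulation_config(kappa = -1), class = "validation_error")
})

test_that("expected pairwise distances follow star-topology path lengths", {
  cfg <- simulation_config(intra_depth = 0.002, inter_depth = 0.073)
  expect_equal(expected_k2p(cfg, "intra"), 0.004)
  expect_equal(expected_k2p(cfg, "inter"), 0.15)
})

test_that("Monte-Carlo means match the closed-form expectations", {
  # small replicate datasets keep the loop fast; expectations do not
  # depend on the per-species counts
  cfg <- simulation_config(n_species = 3, n_per_species = c(4, 4, 4),
                           intra_depth = 0.002, inter_depth = 0.075)
  n_seeds <- 50
  intra_means <- inter_means <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg$seed <- 1000L + s
    sim <- simulate_dataset(cfg)
    dm <- k2p_matrix(sim$dataset)
    part <- partition_distances(dm, sim$dataset)
    intra_means[s] <- mean(part$intra$distance)
    inter_means[s] <- mean(part$inter$distance)
  }
  m_intra <- mean(intra_means); se_intra <- sd(intra_means) / sqrt(n_seeds)
  m_inter <- mean(inter_means); se_inter <- sd(inter_means) / sqrt(n_seeds)
  expect_lt(abs(m_intra - expected_k2p(cfg, "intra")), 3 * se_intra)
  expect_lt(abs(m_inter - expected_k2p(cfg, "inter")), 3 * se_inter)
  expect_gt(m_intra, 0.003); expect_lt(m_intra, 0.005)
  expect_gt(m_inter, 0.13); expect_lt(m_inter, 0.17)
})

test_that("realised composition tracks the target at long sequence lengths", {
  cfg <- simulation_config(seq_length = 6540, seed = 163)
  comp <- base_composition(simulate_dataset(cfg)$dataset$alignment)
  expect_true(all(abs(comp - cfg$base_freqs) < 0.005))
})

test_that("the transition:transversion ratio increases with kappa", {
  ratios <- vapply(c(1, 2, 8), function(k) {
    cfg <- simulation_config(n_species = 2, n_per_species = c(6, 6),
                             seq_length = 2000, kappa = k,
                             intra_depth = 0.01, inter_depth = 0.08, seed = 167)
    sim <- simulate_dataset(cfg)
    aln <- sim$dataset$alignment
    ts <- tv <- 0
    for (i in 1:11) for (j in (i + 1):12) {
      cnt <- count_site_pairs(aln[i, ], aln[j, ])
      ts <- ts + cnt$n_transitions; tv <- tv + cnt$n_transversions
    }
    ts / tv
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("mislabel injection changes exactly the requested specimens", {
  sim <- simulate_dataset(simulation_config(seed = 173))
  expect_identical(inject_mislabels(sim, 0), sim)

  sim5 <- inject_mislabels(sim, 5, seed = 179)
  expect_length(sim5$swapped_ids, 5)
  expect_true(all(sim5$observed_labels[sim5$swapped_ids] !=
                  sim5$true_species[sim5$swapped_ids]))
  untouched <- setdiff(names(sim$true_species), sim5$swapped_ids)
  expect_identical(sim5$observed_labels[untouched], sim5$true_species[untouched])
  # metadata carries the observed labels
  expect_identical(setNames(sim5$dataset$metadata$species_label,
                            sim5$dataset$metadata$specimen_id),
                   sim5$observed_labels)

  single <- simulate_dataset(simulation_config(n_species = 1, n_per_species = 8,
                                               seed = 181))
  expect_error(inject_mislabels(single, 1), class = "validation_error")
})

test_that("well-separated simulations let congruence recover the swaps end-to-end", {
  cfg <- simulation_config(inter_depth = 0.073, n_mislabels = 5, seed = 191)
  sim <- simulate_dataset(cfg)
  dm <- k2p_matrix(sim$dataset)
  thr <- optimise_threshold(dm)$selected
  part <- delimit_motus(dm, thr)
  cong <- congruence_report(part, sim$dataset)
  expect_length(part$motus, 5)
  expect_setequal(cong$mismatches$specimen_id, sim$swapped_ids)
})
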