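test_that("partitioning is exhaustive and matches species combinatorics", {
  ds <- toy_dataset()
  dm <- k2p_matrix(ds)
  part <- partition_distances(dm, ds)
  expect_equal(nrow(part$intra), 2)  # 2 species x C(2,2)
  expect_equal(nrow(part$inter), 4)
  expect_equal(nrow(part$intra) + nrow(part$inter), 4 * 3 / 2)

  # paper-shaped study: counts {9,12,4,11,20} -> sum n_k(n_k-1)/2 = 353 intra
  sim <- simulate_dataset(simulation_config(inter_depth = 0.073, seed = 3))
  dms <- k2p_matrix(sim$dataset)
  ps <- partition_distances(dms, sim$dataset)
  counts <- c(9, 12, 4, 11, 20)
  expect_equal(nrow(ps$intra), sum(counts * (counts - 1) / 2))
  expect_equal(nrow(ps$intra), 353)
  expect_equal(nrow(ps$inter), 56 * 55 / 2 - 353)
})

test_that("a single-species dataset cannot be partitioned", {
  seqs <- c(a = "ACGTACGTAC", b = "ACGTACGTAT", c = "ACGTACGTAG")
  meta <- data.frame(specimen_id = names(seqs), species_label = "only_one")
  ds <- build_dataset(barcode_alignment(seqs), meta)
  expect_error(partition_distances(k2p_matrix(ds), ds),
               class = "single_species_error")
})

test_that("outgroup-flagged specimens are excluded from the partition", {
  ds <- toy_dataset()
  ds$metadata$outgroup <- c(FALSE, FALSE, FALSE, TRUE)
  dm <- k2p_matrix(ds)
  part <- partition_distances(dm, ds)
  expect_equal(nrow(part$intra) + nrow(part$inter), 3 * 2 / 2)
  expect_false("b2" %in% c(part$intra$id_a, part$intra$id_b,
                           part$inter$id_a, part$inter$id_b))
})

test_that("the rank-sum p-value matches exhaustive enumeration", {
  # frozen textbook case: intra {1,2} vs inter {3,4} -> exact two-sided 1/3
  part <- structure(list(
    intra = data.frame(id_a = "a", id_b = "b", distance = c(1, 2)),
    inter = data.frame(id_a = "c", id_b = "d", distance = c(3, 4))),
    class = "distance_partition")
  g <- gap_summary(part)
  expect_equal(g$wilcoxon_p, 1 / 3, tolerance = 1e-12)
  expect_equal(g$wilcoxon_p, oracle_wilcoxon_p(part$inter$distance,
                                               part$intra$distance))

  set.seed(61)
  for (rep in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    vals <- sample(seq(0.001, 0.2, by = 0.001), n1 + n2)  # distinct -> no ties
    intra <- vals[seq_len(n1)]; inter <- vals[-seq_len(n1)]
    p <- structure(list(intra = data.frame(id_a = "x", id_b = "y", distance = intra),
                        inter = data.frame(id_a = "x", id_b = "y", distance = inter)),
                   class = "distance_partition")
    expect_equal(gap_summary(p)$wilcoxon_p, oracle_wilcoxon_p(inter, intra),
                 tolerance = 1e-12)
  }
})

test_that("gap summary reports medians, extremes and the gap flags", {
  part <- structure(list(
    intra = data.frame(id_a = "a", id_b = "b", distance = c(0.001, 0.002, 0.004)),
    inter = data.frame(id_a = "c", id_b = "d", distance = c(0.1, 0.12, 0.15))),
    class = "distance_partition")
  g <- gap_summary(part)
  expect_equal(g$intra_median, 0.002)
  expect_equal(g$inter_median, 0.12)
  expect_true(g$gap_by_median)
  expect_true(g$gap_by_extremes)  # min inter 0.1 > max intra 0.004

  # even counts use the midpoint convention
  part$intra <- data.frame(id_a = "a", id_b = "b", distance = c(0.001, 0.003))
  expect_equal(gap_summary(part)$intra_median, 0.002)
})

test_that("synthetic data at study-like divergence shows a strong gap", {
  sim <- simulate_dataset(simulation_config(inter_depth = 0.073, seed = 9))
  dm <- k2p_matrix(sim$dataset)
  g <- gap_summary(partition_distances(dm, sim$dataset))
  expect_gt(g$inter_median, g$intra_median)
  expect_lt(g$wilcoxon_p, 0.001)
  expect_lt(g$wilcoxon_p_greater, 0.001)
})

test_that("the per-specimen gap table flags gapped and gapless specimens", {
  # sp_a: a1,a2,a3; sp_b: b1. a3 is closer to b1 than to its conspecifics.
  d <- matrix(0, 4, 4)
  ids <- c("a1", "a2", "a3", "b1")
  d[1, 2] <- 0.01; d[1, 3] <- 0.05; d[2, 3] <- 0.05
  d[1, 4] <- 0.12; d[2, 4] <- 0.12; d[3, 4] <- 0.003
  d <- d + t(d)
  dm <- make_dm(d, ids)
  meta <- data.frame(specimen_id = ids,
                     species_label = c("sp_a", "sp_a", "sp_a", "sp_b"))
  aln <- barcode_alignment(c(a1 = "ACGT", a2 = "ACGT", a3 = "ACGT", b1 = "ACGT"))
  ds <- build_dataset(aln, meta)

  tab <- specimen_gap_table(dm, ds)
  expect_equal(tab$max_intra[tab$specimen_id == "a1"], 0.05)
  expect_equal(tab$min_inter[tab$specimen_id == "a1"], 0.12)
  expect_true(tab$has_gap[tab$specimen_id == "a1"])
  # nearest non-conspecific closer than furthest conspecific: no gap
  expect_false(tab$has_gap[tab$specimen_id == "a3"])
  # singleton species: max_intra and has_gap undefined
  expect_true(is.na(tab$max_intra[tab$specimen_id == "b1"]))
  expect_true(is.na(tab$has_gap[tab$specimen_id == "b1"]))
})

test_that("well-separated simulations give every specimen a gap", {
  cfg <- simulation_config(n_species = 3, n_per_species = c(5, 6, 5),
                           intra_depth = 0.002, inter_depth = 0.05, seed = 13)
  sim <- simulate_dataset(cfg)
  dm <- k2p_matrix(sim$dataset)
  tab <- specimen_gap_table(dm, sim$dataset)
  expect_true(all(tab$has_gap))
})

test_that("boxplot series reproduce quartiles and 1.5 IQR whiskers", {
  set.seed(71)
  intra <- runif(40, 0, 0.01)
  inter <- c(runif(40, 0.1, 0.16), 0.5)  # one far outlier
  part <- structure(list(intra = data.frame(id_a = "x", id_b = "y", distance = intra),
                         inter = data.frame(id_a = "x", id_b = "y", distance = inter)),
                    class = "distance_partition")
  bp <- boxplot_series(part)
  expect_equal(bp$median[bp$partition == "inter"], median(inter))
  expect_true(0.5 %in% bp$outliers[[which(bp$partition == "inter")]])
  expect_lte(bp$whisker_high[bp$partition == "inter"],
             bp$q3[bp$partition == "inter"] + 1.5 * (bp$q3[bp$partition == "inter"] -
                                                     bp$q1[bp$partition == "inter"]))
})
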