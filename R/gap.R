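# Barcode-gap assessment: intra- vs interspecific distance partitions,
# rank-sum test, and the per-specimen gap table underlying the classic
# line-plot diagnostic (nearest non-conspecific vs furthest conspecific).

#' Partition pairwise distances into intra- and interspecific sets
#'
#' Every unordered off-diagonal pair lands in exactly one set according to
#' whether the two specimens share a species label. Specimens whose
#' metadata flags them as `outgroup` are excluded entirely.
#'
#' @param dm a `k2p_dist` from [k2p_matrix()].
#' @param dataset the matching `barcode_dataset`.
#' @return A `distance_partition`: list of data.frames `intra` and `inter`
#'   with columns `id_a`, `id_b`, `distance`.
#' @export
partition_distances <- function(dm, dataset) {
  labels <- species_labels(dataset)
  keep <- dm$ids
  og <- dataset$metadata$outgroup
  if (!is.null(og)) {
    out_ids <- dataset$metadata$specimen_id[which(og)]
    keep <- setdiff(keep, out_ids)
  }
  if (!all(keep %in% names(labels))) {
    stop_barcodegap("join", "distance matrix contains unlabeled specimens: %s",
                    .fmt_ids(setdiff(keep, names(labels))))
  }
  n <- length(keep)
  if (n < 2L) stop_barcodegap("precondition", "need at least 2 non-outgroup specimens")
  idx <- which(lower.tri(diag(n)), arr.ind = TRUE)
  id_a <- keep[idx[, "col"]]
  id_b <- keep[idx[, "row"]]
  dist <- dm$d[cbind(match(id_b, dm$ids), match(id_a, dm$ids))]
  same <- labels[id_a] == labels[id_b]
  pairs <- data.frame(id_a = id_a, id_b = id_b, distance = dist,
                      stringsAsFactors = FALSE)
  part <- structure(list(intra = pairs[same, , drop = FALSE],
                         inter = pairs[!same, , drop = FALSE]),
                    class = "distance_partition")
  if (nrow(part$inter) == 0L) {
    stop_barcodegap("single_species",
      "all specimens share one species label; no interspecific distances")
  }
  rownames(part$intra) <- rownames(part$inter) <- NULL
  part
}

#' Summarise the barcode gap and test intra vs inter distances
#'
#' Medians, ranges, and the Wilcoxon rank-sum test comparing interspecific
#' with intraspecific distances. The test is exact when both samples have
#' at most 25 values and no ties, otherwise the normal approximation with
#' tie and continuity corrections is used. Both the two-sided p-value and
#' the one-sided p-value for inter > intra are reported. Note pairwise
#' distances are not independent observations; the test replicates the
#' conventional barcoding usage and should be read descriptively.
#'
#' @param partition a `distance_partition`.
#' @return A `gap_summary` list: `intra_median`, `intra_min`, `intra_max`,
#'   `inter_median`, `inter_min`, `inter_max`, `n_intra`, `n_inter`,
#'   `wilcoxon_p` (two-sided), `wilcoxon_p_greater` (inter > intra),
#'   `wilcoxon_exact`, `gap_by_median`, `gap_by_extremes`.
#' @export
gap_summary <- function(partition) {
  intra <- partition$intra$distance
  inter <- partition$inter$distance
  intra <- intra[!is.na(intra)]
  inter <- inter[!is.na(inter)]
  if (length(intra) == 0L || length(inter) == 0L) {
    stop_barcodegap("precondition", "both intra- and interspecific sets must be non-empty")
  }
  use_exact <- length(intra) <= 25 && length(inter) <= 25 &&
    !anyDuplicated(c(intra, inter))
  two <- suppressWarnings(stats::wilcox.test(inter, intra, alternative = "two.sided",
                                             exact = use_exact, correct = TRUE))
  gt <- suppressWarnings(stats::wilcox.test(inter, intra, alternative = "greater",
                                            exact = use_exact, correct = TRUE))
  structure(list(
    intra_median = stats::median(intra), intra_min = min(intra), intra_max = max(intra),
    inter_median = stats::median(inter), inter_min = min(inter), inter_max = max(inter),
    n_intra = length(intra), n_inter = length(inter),
    wilcoxon_p = two$p.value, wilcoxon_p_greater = gt$p.value,
    wilcoxon_exact = use_exact,
    gap_by_median = stats::median(inter) > stats::median(intra),
    gap_by_extremes = min(inter) > max(intra)
  ), class = "gap_summary")
}

#' @export
print.gap_summary <- function(x, ...) {
  cat(sprintf("intra: median %.3f range %.3f-%.3f (n=%d)\n",
              x$intra_median, x$intra_min, x$intra_max, x$n_intra))
  cat(sprintf("inter: median %.3f range %.3f-%.3f (n=%d)\n",
              x$inter_median, x$inter_min, x$inter_max, x$n_inter))
  cat(sprintf("Wilcoxon rank-sum (%s): two-sided p = %.3g; inter>intra p = %.3g\n",
              if (x$wilcoxon_exact) "exact" else "normal approx.",
              x$wilcoxon_p, x$wilcoxon_p_greater))
  cat(sprintf("gap by medians: %s; gap by extremes (min inter > max intra): %s\n",
              x$gap_by_median, x$gap_by_extremes))
  cat("note: pairwise distances are non-independent; p-values are descriptive\n")
  invisible(x)
}

#' Per-specimen barcode-gap table
#'
#' For each specimen: the distance to its furthest conspecific
#' (`max_intra`, `NA` for singleton species), the distance to its nearest
#' non-conspecific (`min_inter`), and whether a gap exists for the
#' specimen (`has_gap = min_inter > max_intra`, `NA` for singletons).
#'
#' @param dm a `k2p_dist`.
#' @param dataset the matching `barcode_dataset`.
#' @return data.frame with columns `specimen_id`, `species_label`,
#'   `max_intra`, `min_inter`, `has_gap`.
#' @export
specimen_gap_table <- function(dm, dataset) {
  labels <- species_labels(dataset)[dm$ids]
  if (length(unique(labels)) < 2L) {
    stop_barcodegap("precondition", "need at least 2 species")
  }
  n <- length(dm$ids)
  res <- lapply(seq_len(n), function(i) {
    d_i <- dm$d[i, -i]
    lab_i <- labels[-i]
    con <- d_i[lab_i == labels[i]]
    het <- d_i[lab_i != labels[i]]
    max_intra <- if (length(con)) max(con, na.rm = TRUE) else NA_real_
    min_inter <- min(het, na.rm = TRUE)
    data.frame(specimen_id = dm$ids[i], species_label = unname(labels[i]),
               max_intra = max_intra, min_inter = min_inter,
               has_gap = if (is.na(max_intra)) NA else min_inter > max_intra,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Boxplot data series for intra/inter distance distributions
#'
#' Quartiles, whiskers at 1.5 IQR and outliers for each partition, i.e. the
#' underlying data of the standard gap boxplot.
#'
#' @param partition a `distance_partition`.
#' @return data.frame, one row per partition, with list-column `outliers`.
#' @export
boxplot_series <- function(partition) {
  one <- function(v, which) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(v[v >= q[1] - 1.5 * iqr])
    hi <- max(v[v <= q[3] + 1.5 * iqr])
    data.frame(partition = which, q1 = q[1], median = q[2], q3 = q[3],
               whisker_low = lo, whisker_high = hi,
               outliers = I(list(v[v < lo | v > hi])),
               stringsAsFactors = FALSE)
  }
  rbind(one(partition$intra$distance[!is.na(partition$intra$distance)], "intra"),
        one(partition$inter$distance[!is.na(partition$inter$distance)], "inter"))
}
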