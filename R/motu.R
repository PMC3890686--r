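# Threshold-linked MOTU delimitation (single-linkage chaining) and
# congruence with morphospecies labels. Two specimens fall in one MOTU iff
# a chain of specimens links them with every consecutive distance at or
# below the threshold -- so two specimens further apart than the threshold
# still share a MOTU when both are within it of a third.

#' Delimit MOTUs by single-linkage chaining at a threshold
#'
#' MOTUs are the connected components of the graph with an edge wherever
#' `d <= threshold` (inclusive). MOTU labels are content-derived: clusters
#' are ordered by decreasing size, ties by the lexicographically smallest
#' member, so the partition and its labels are invariant to input order.
#'
#' @param dm a `k2p_dist`.
#' @param threshold linking distance (>= 0).
#' @return A `motu_partition`: list with `threshold`, `motus` (list of
#'   sorted specimen-ID vectors) and `assignments` (named character vector
#'   specimen -> MOTU label).
#' @export
delimit_motus <- function(dm, threshold) {
  if (threshold < 0) stop_barcodegap("precondition", "threshold must be >= 0")
  adj <- !is.na(dm$d) & dm$d <= threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  motus <- split(dm$ids, comp)
  motus <- lapply(motus, sort)
  ord <- order(-lengths(motus), vapply(motus, `[`, character(1), 1L))
  motus <- unname(motus[ord])
  names(motus) <- sprintf("MOTU_%02d", seq_along(motus))
  assignments <- stats::setNames(rep(names(motus), lengths(motus)), unlist(motus))
  assignments <- assignments[dm$ids]
  structure(list(threshold = threshold, motus = motus, assignments = assignments),
            class = "motu_partition")
}

#' @export
print.motu_partition <- function(x, ...) {
  cat(sprintf("motu_partition: %d MOTUs at threshold %.4f (sizes: %s)\n",
              length(x$motus), x$threshold,
              paste(lengths(x$motus), collapse = ", ")))
  invisible(x)
}

#' Congruence of MOTUs with morphospecies labels
#'
#' Cross-tabulates MOTU membership against species labels and lists every
#' specimen whose label differs from the majority label of its MOTU (the
#' putative misidentifications). Majority ties are broken by the
#' lexicographically first species and flagged.
#'
#' @param partition a `motu_partition`.
#' @param dataset the matching `barcode_dataset` (or `labels` directly).
#' @param labels optional named label vector overriding the dataset labels.
#' @return A `congruence_report`: list with `composition` (long data.frame
#'   motu x species counts), `species_spread` (MOTUs per species),
#'   `mismatches` (data.frame `specimen_id`, `species_label`, `motu_id`,
#'   `majority_species`, `majority_tie`).
#' @export
congruence_report <- function(partition, dataset = NULL, labels = NULL) {
  if (is.null(labels)) labels <- species_labels(dataset)
  if (length(partition$motus) == 0L) stop_barcodegap("precondition", "empty partition")
  ids <- names(partition$assignments)
  lab <- labels[ids]
  if (anyNA(lab)) {
    stop_barcodegap("join", "missing species labels for: %s",
                    .fmt_ids(ids[is.na(lab)]))
  }
  comp <- as.data.frame(table(motu_id = partition$assignments[ids],
                              species_label = lab),
                        stringsAsFactors = FALSE)
  names(comp)[3] <- "n"
  comp <- comp[comp$n > 0, , drop = FALSE]
  comp <- comp[order(comp$motu_id, comp$species_label), , drop = FALSE]
  rownames(comp) <- NULL

  spread <- as.data.frame(
    tapply(partition$assignments[ids], lab,
           function(m) length(unique(m))))
  species_spread <- data.frame(species_label = rownames(spread),
                               n_motus = as.integer(spread[[1]]),
                               stringsAsFactors = FALSE)
  rownames(species_spread) <- NULL

  mism <- lapply(names(partition$motus), function(mid) {
    members <- partition$motus[[mid]]
    tab <- table(lab[members])
    winners <- names(tab)[tab == max(tab)]
    majority <- sort(winners)[1]
    tie <- length(winners) > 1L
    off <- members[lab[members] != majority]
    if (length(off) == 0L) return(NULL)
    data.frame(specimen_id = off, species_label = unname(lab[off]),
               motu_id = mid, majority_species = majority,
               majority_tie = tie, stringsAsFactors = FALSE)
  })
  mismatches <- do.call(rbind, mism)
  if (is.null(mismatches)) {
    mismatches <- data.frame(specimen_id = character(0), species_label = character(0),
                             motu_id = character(0), majority_species = character(0),
                             majority_tie = logical(0), stringsAsFactors = FALSE)
  }
  rownames(mismatches) <- NULL
  structure(list(composition = comp, species_spread = species_spread,
                 mismatches = mismatches),
            class = "congruence_report")
}

#' @export
print.congruence_report <- function(x, ...) {
  cat(sprintf("congruence_report: %d MOTUs x %d species; %d label/MOTU mismatch(es)\n",
              length(unique(x$composition$motu_id)),
              length(unique(x$composition$species_label)),
              nrow(x$mismatches)))
  if (nrow(x$mismatches)) print(x$mismatches)
  invisible(x)
}

#' MOTU counts across a grid of thresholds
#'
#' @param dm a `k2p_dist`.
#' @param thresholds ascending numeric vector of thresholds.
#' @return data.frame `threshold`, `n_motus` (non-increasing).
#' @export
motu_count_curve <- function(dm, thresholds) {
  if (is.unsorted(thresholds)) {
    stop_barcodegap("precondition", "thresholds must be sorted ascending")
  }
  data.frame(threshold = thresholds,
             n_motus = vapply(thresholds,
                              function(t) length(delimit_motus(dm, t)$motus),
                              numeric(1)))
}

#' Single-linkage dendrogram of a distance matrix as newick
#'
#' Companion visualisation of the chaining structure: cutting this
#' dendrogram at height = threshold reproduces [delimit_motus()] exactly
#' (single linkage merges clusters at the smallest linking distance).
#' Following the usual ultrametric convention, tips sit at depth
#' merge-height/2, so two specimens at distance `d` join at height `d`
#' with branch lengths `d/2`.
#'
#' @param dm a `k2p_dist` with at least 2 specimens.
#' @return newick string (single line, terminated with `;`).
#' @export
linkage_to_newick <- function(dm) {
  if (length(dm$ids) < 2L) stop_barcodegap("precondition", "need at least 2 specimens")
  hc <- stats::hclust(stats::as.dist(dm$d), method = "single")
  ape::write.tree(ape::as.phylo(hc))
}
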