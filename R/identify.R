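# Leave-one-out specimen identification. Each specimen in turn is the
# query; all remaining specimens are the reference database. Three
# criteria:
#   * best close match -- nearest individual(s) within a threshold;
#     outcomes correct / incorrect / ambiguous / no_id,
#   * near neighbour   -- is any tied-nearest individual conspecific?
#     outcomes true / false,
#   * threshold ID     -- every individual within a fixed radius (1% by
#     convention, emulating the BOLD "Identify Specimen" rule); outcomes
#     correct / incorrect / ambiguous / no_id.

# Distances within this relative tolerance of the minimum count as tied;
# exact float equality is too brittle for recomputed matrices.
TIE_TOL <- 1e-12

.loo <- function(query, dm, labels, query_labels = labels) {
  i <- match(query, dm$ids)
  if (is.na(i)) stop_barcodegap("precondition", "unknown specimen '%s'", query)
  if (length(dm$ids) < 2L) stop_barcodegap("precondition", "need at least 2 specimens")
  d <- dm$d[i, -i]
  list(d = d, labels = labels[dm$ids[-i]], ids = dm$ids[-i],
       query_label = unname(query_labels[query]))
}

.tied_nearest <- function(d) {
  m <- min(d, na.rm = TRUE)
  which(d <= m + TIE_TOL * max(m, 1))
}

.outcome <- function(specimen_id, criterion, outcome, matched_ids) {
  data.frame(specimen_id = specimen_id, criterion = criterion,
             outcome = outcome,
             matched_ids = paste(matched_ids, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Best-close-match identification of one specimen
#'
#' The query's nearest non-self individual(s) are examined. If the nearest
#' distance exceeds the threshold the outcome is `no_id`; otherwise the
#' tied-nearest set decides: all conspecific -> `correct`, all
#' heterospecific -> `incorrect`, mixed -> `ambiguous`.
#'
#' @param query specimen ID.
#' @param dm a `k2p_dist`.
#' @param labels named character vector of species labels (names = IDs).
#' @param threshold distance threshold (typically the optimised one).
#' @param query_labels labels used for the query side (defaults to
#'   `labels`); pass the observed field identifications here, with trusted
#'   reference labels in `labels`, to screen for misidentified specimens.
#' @return one-row data.frame: `specimen_id`, `criterion`, `outcome`,
#'   `matched_ids` (comma-separated supporting IDs, empty for `no_id`).
#' @export
best_close_match <- function(query, dm, labels, threshold, query_labels = labels) {
  x <- .loo(query, dm, labels, query_labels)
  m <- min(x$d, na.rm = TRUE)
  if (m > threshold) return(.outcome(query, "best_close_match", "no_id", character(0)))
  near <- .tied_nearest(x$d)
  same <- x$labels[near] == x$query_label
  out <- if (all(same)) "correct" else if (!any(same)) "incorrect" else "ambiguous"
  .outcome(query, "best_close_match", out, x$ids[near])
}

#' Near-neighbour identification of one specimen
#'
#' `true` iff at least one of the tied-nearest individuals is conspecific
#' with the query, else `false`. No threshold is involved.
#'
#' @inheritParams best_close_match
#' @return one-row data.frame as in [best_close_match()].
#' @export
near_neighbour <- function(query, dm, labels, query_labels = labels) {
  x <- .loo(query, dm, labels, query_labels)
  near <- .tied_nearest(x$d)
  out <- if (any(x$labels[near] == x$query_label)) "true" else "false"
  .outcome(query, "near_neighbour", out, x$ids[near])
}

#' Fixed-threshold identification of one specimen
#'
#' Considers every individual within `threshold` of the query (inclusive;
#' default 1%, the BOLD convention). Empty set -> `no_id`; all conspecific
#' -> `correct`; both conspecific and heterospecific -> `ambiguous`; only
#' heterospecific -> `incorrect`.
#'
#' @inheritParams best_close_match
#' @param threshold fixed radius in substitutions/site (default `0.01`).
#' @return one-row data.frame as in [best_close_match()].
#' @export
thresh_id <- function(query, dm, labels, threshold = 0.01, query_labels = labels) {
  x <- .loo(query, dm, labels, query_labels)
  within <- which(!is.na(x$d) & x$d <= threshold)
  if (length(within) == 0L) return(.outcome(query, "thresh_id", "no_id", character(0)))
  same <- x$labels[within] == x$query_label
  out <- if (all(same)) "correct" else if (!any(same)) "incorrect" else "ambiguous"
  .outcome(query, "thresh_id", out, x$ids[within])
}

#' Leave-one-out identification report under all three criteria
#'
#' Scores every specimen under best close match, near neighbour and
#' threshold ID, and tabulates counts and percentages per criterion and
#' outcome (percentages half-up rounded to 2 decimals).
#'
#' @param dataset a `barcode_dataset` (used for species labels), or `NULL`
#'   if `labels` is given.
#' @param dm a `k2p_dist`.
#' @param bcm_threshold threshold for best close match (typically from
#'   [optimise_threshold()]).
#' @param tid_threshold fixed radius for threshold ID (default `0.01`).
#' @param labels optional named label vector overriding the dataset labels
#'   (e.g. true species in a simulation study).
#' @param query_labels optional label vector for the query side only (see
#'   [best_close_match()]); defaults to `labels`.
#' @return An `identification_report`: list with `outcomes` (long
#'   data.frame), `summary` (criterion x outcome with `n` and `pct`),
#'   `thresholds`.
#' @export
evaluate_all <- function(dataset, dm, bcm_threshold, tid_threshold = 0.01,
                         labels = NULL, query_labels = NULL) {
  if (is.null(labels)) labels <- species_labels(dataset)
  if (is.null(query_labels)) query_labels <- labels
  if (length(unique(labels[dm$ids])) < 2L) {
    stop_barcodegap("precondition", "identification tests need at least 2 species")
  }
  rows <- lapply(dm$ids, function(id) {
    rbind(best_close_match(id, dm, labels, bcm_threshold, query_labels),
          near_neighbour(id, dm, labels, query_labels),
          thresh_id(id, dm, labels, tid_threshold, query_labels))
  })
  outcomes <- do.call(rbind, rows)
  n <- length(dm$ids)
  vocab <- list(best_close_match = c("correct", "incorrect", "ambiguous", "no_id"),
                near_neighbour = c("true", "false"),
                thresh_id = c("correct", "incorrect", "ambiguous", "no_id"))
  summary <- do.call(rbind, lapply(names(vocab), function(cr) {
    sub <- outcomes[outcomes$criterion == cr, ]
    counts <- vapply(vocab[[cr]], function(o) sum(sub$outcome == o), numeric(1))
    data.frame(criterion = cr, outcome = vocab[[cr]], n = as.integer(counts),
               pct = round_half_up(100 * counts / n, 2),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(outcomes = outcomes, summary = summary,
                 thresholds = c(best_close_match = bcm_threshold,
                                thresh_id = tid_threshold),
                 n_specimens = n),
            class = "identification_report")
}

#' @export
print.identification_report <- function(x, ...) {
  cat(sprintf("Leave-one-out identification, %d specimens\n", x$n_specimens))
  cat(sprintf("thresholds: best close match %.4f, threshold ID %.4f\n",
              x$thresholds["best_close_match"], x$thresholds["thresh_id"]))
  for (cr in unique(x$summary$criterion)) {
    sub <- x$summary[x$summary$criterion == cr, ]
    cat(sprintf("  %-16s %s\n", cr,
                paste(sprintf("%s %d (%.2f%%)", sub$outcome, sub$n, sub$pct),
                      collapse = "  ")))
  }
  invisible(x)
}
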