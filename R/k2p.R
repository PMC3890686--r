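# Kimura 2-parameter distances with pairwise deletion.
#
# A column contributes to a pair only when both residues are unambiguous
# bases (A/C/G/T): gaps, N and IUPAC ambiguity codes are treated as missing
# for that pair, never partially matched. Transitions are A<->G and C<->T;
# every other differing comparable pair is a transversion.

#' Count comparable sites, transitions and transversions for one pair
#'
#' @param seq_a,seq_b aligned sequences of equal length, as strings or
#'   character vectors.
#' @return list with `n_sites`, `n_transitions`, `n_transversions`, and the
#'   proportions `P` (transitions) and `Q` (transversions); class
#'   `site_pair_counts`.
#' @export
count_site_pairs <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1L && nchar(seq_a) > 1L) strsplit(seq_a, "")[[1]] else as.character(seq_a)
  b <- if (length(seq_b) == 1L && nchar(seq_b) > 1L) strsplit(seq_b, "")[[1]] else as.character(seq_b)
  if (length(a) != length(b)) {
    stop_barcodegap("alignment", "sequences differ in length (%d vs %d)",
                    length(a), length(b))
  }
  a <- toupper(a); b <- toupper(b)
  bases <- c("A", "C", "G", "T")
  ok <- a %in% bases & b %in% bases
  n <- sum(ok)
  if (n == 0L) {
    stop_barcodegap("incomparable_pair", "no comparable sites between the two sequences")
  }
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ts <- diff & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                (a == "C" & b == "T") | (a == "T" & b == "C"))
  n_ts <- sum(ts)
  n_tv <- sum(diff) - n_ts
  structure(list(n_sites = n, n_transitions = n_ts, n_transversions = n_tv,
                 P = n_ts / n, Q = n_tv / n),
            class = "site_pair_counts")
}

#' Kimura 2-parameter distance from site-pair counts
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where `P` and `Q` are the
#' observed proportions of transition and transversion differences over the
#' comparable sites. When either logarithm argument is non-positive the
#' divergence has saturated and the distance is undefined.
#'
#' @param counts a `site_pair_counts`, or a list/vector with elements `P`
#'   and `Q`.
#' @return distance in substitutions/site (non-negative scalar).
#' @export
k2p_distance <- function(counts) {
  P <- counts$P
  Q <- counts$Q
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop_barcodegap("saturation",
      "K2P distance undefined (saturated): P = %.4f, Q = %.4f", P, Q)
  }
  max(0, -0.5 * log(w1) - 0.25 * log(w2))
}

#' Pairwise K2P distance matrix for a dataset
#'
#' Computes all pairwise K2P distances with pairwise deletion of
#' gap/ambiguous columns. By default any saturated or incomparable pair is
#' an error naming the pair; with `on_saturation = "na"` such pairs are
#' recorded as `NA` with a warning and excluded from downstream pooling.
#'
#' @param x a `barcode_dataset` or a [barcode_alignment()].
#' @param on_saturation `"error"` (default) or `"na"`.
#' @return A `k2p_dist`: list with `ids`, `d` (symmetric distance matrix)
#'   and `n_sites` (matrix of comparable-site counts per pair).
#' @export
k2p_matrix <- function(x, on_saturation = c("error", "na")) {
  on_saturation <- match.arg(on_saturation)
  alignment <- if (inherits(x, "barcode_dataset")) x$alignment else x
  n <- nrow(alignment)
  if (n < 2L) stop_barcodegap("precondition", "need at least 2 specimens")
  ids <- rownames(alignment)

  # integer coding: A=1 C=2 G=3 T=4, everything else NA (missing for the pair)
  code <- match(alignment, c("A", "C", "G", "T"))
  dim(code) <- dim(alignment)

  d <- matrix(0, n, n, dimnames = list(ids, ids))
  ns <- matrix(ncol(alignment), n, n, dimnames = list(ids, ids))
  bad_pairs <- character(0)
  for (i in seq_len(n - 1L)) {
    ai <- code[i, ]
    for (j in seq(i + 1L, n)) {
      bj <- code[j, ]
      ok <- !is.na(ai) & !is.na(bj)
      m <- sum(ok)
      ns[i, j] <- ns[j, i] <- m
      if (m == 0L) {
        if (on_saturation == "error") {
          stop_barcodegap("incomparable_pair",
            "no comparable sites for pair %s / %s", ids[i], ids[j])
        }
        d[i, j] <- d[j, i] <- NA_real_
        bad_pairs <- c(bad_pairs, paste(ids[i], ids[j], sep = "/"))
        next
      }
      a <- ai[ok]; b <- bj[ok]
      diffs <- a != b
      # transitions: {1,3} (A/G) or {2,4} (C/T) <=> codes differ by exactly 2
      n_ts <- sum(diffs & abs(a - b) == 2L)
      n_tv <- sum(diffs) - n_ts
      P <- n_ts / m; Q <- n_tv / m
      w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
      if (w1 <= 0 || w2 <= 0) {
        if (on_saturation == "error") {
          stop_barcodegap("saturation",
            "saturated pair %s / %s (P = %.4f, Q = %.4f)", ids[i], ids[j], P, Q)
        }
        d[i, j] <- d[j, i] <- NA_real_
        bad_pairs <- c(bad_pairs, paste(ids[i], ids[j], sep = "/"))
        next
      }
      d[i, j] <- d[j, i] <- max(0, -0.5 * log(w1) - 0.25 * log(w2))
    }
  }
  if (length(bad_pairs)) {
    warning(sprintf("%d pair(s) saturated/incomparable, recorded as NA: %s",
                    length(bad_pairs), .fmt_ids(bad_pairs)), call. = FALSE)
  }
  structure(list(ids = ids, d = d, n_sites = ns), class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  v <- x$d[lower.tri(x$d)]
  cat(sprintf("k2p_dist: %d specimens, %d pairs; range %.4f-%.4f (%d NA)\n",
              length(x$ids), length(v), min(v, na.rm = TRUE),
              max(v, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

#' Lower-triangle distances of a `k2p_dist`
#' @param dm a `k2p_dist`.
#' @param drop_na drop NA (saturated/incomparable) entries.
#' @return numeric vector of pairwise distances.
#' @export
pairwise_values <- function(dm, drop_na = TRUE) {
  v <- dm$d[lower.tri(dm$d)]
  if (drop_na) v <- v[!is.na(v)]
  v
}

#' Write / read a square distance matrix as TSV
#'
#' Square tab-separated layout with specimen IDs as both header row and
#' first column, full double precision.
#'
#' @param dm a `k2p_dist` (or list with `ids`, `d`).
#' @param path file path.
#' @return `path` (writer) / a `k2p_dist` with `n_sites = NA` (reader).
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(specimen_id = dm$ids,
                   format(dm$d, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  names(df) <- c("specimen_id", dm$ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  d <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  dimnames(d) <- list(ids, ids)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop_barcodegap("io", "distance matrix in %s is not symmetric", path)
  }
  ns <- matrix(NA_integer_, length(ids), length(ids), dimnames = list(ids, ids))
  structure(list(ids = ids, d = d, n_sites = ns), class = "k2p_dist")
}
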