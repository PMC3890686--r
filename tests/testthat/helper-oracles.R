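# Shared fixtures and independent oracles used across the suite.

# Random aligned matrix: every row is a mutated copy of one reference
# sequence (per-site substitution probability p_sub keeps pairs far from
# K2P saturation), optionally salted with gaps and Ns (missing data for
# pairwise deletion).
random_alignment <- function(n, len, p_missing = 0, p_sub = 0.08) {
  pool <- c("A", "C", "G", "T")
  ref <- sample(pool, len, replace = TRUE)
  mat <- matrix(ref, n, len, byrow = TRUE)
  for (i in seq_len(n)) {
    hit <- which(runif(len) < p_sub)
    for (j in hit) mat[i, j] <- sample(setdiff(pool, mat[i, j]), 1)
  }
  if (p_missing > 0) {
    miss <- runif(n * len) < p_missing
    mat[miss] <- sample(c("-", "N"), sum(miss), replace = TRUE)
  }
  rownames(mat) <- sprintf("sp%02d", seq_len(n))
  barcode_alignment(mat)
}

# Independent K2P oracle: recount transitions/transversions with string
# logic unrelated to the implementation's integer coding, then apply the
# closed form.
oracle_k2p <- function(a, b) {
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  pur <- function(x) x %in% c("A", "G")
  ts <- sum(a != b & pur(a) == pur(b))
  tv <- sum(a != b & pur(a) != pur(b))
  P <- ts / n; Q <- tv / n
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# C(n1+n2, n1) group assignments of the pooled values (no-ties inputs),
# mirroring the standard doubling rule for the two-sided p.
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  p <- if (u_obs > mu) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(1, p)
}

# Brute-force single-linkage clustering: transitive closure of the
# "within threshold" relation via boolean matrix powering.
oracle_components <- function(d, threshold) {
  n <- nrow(d)
  adj <- d <= threshold
  diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(n)) reach <- (reach %*% adj) > 0
  groups <- unique(lapply(seq_len(n), function(i) which(reach[i, ])))
  lapply(groups, function(g) sort(rownames(d)[g]))
}

# Random symmetric distance matrix wrapped as a k2p_dist-alike.
random_dm <- function(n, max_d = 0.2) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, max_d)
  d <- d + t(d)
  ids <- sprintf("sp%02d", seq_len(n))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d,
                 n_sites = matrix(100L, n, n, dimnames = dimnames(d))),
            class = "k2p_dist")
}

# Hand-built k2p_dist from an explicit matrix (for identification toys).
make_dm <- function(d, ids = NULL) {
  if (is.null(ids)) ids <- rownames(d)
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d,
                 n_sites = matrix(100L, nrow(d), nrow(d), dimnames = dimnames(d))),
            class = "k2p_dist")
}

# Small two-species dataset with hand-written sequences (divergence kept
# well below K2P saturation).
toy_dataset <- function() {
  seqs <- c(a1 = "ACGTACGTACGTACGTACGT",
            a2 = "GCGTACGTACGTACGTACGT",   # 1 diff from a1
            b1 = "ACTTACGAACGTACTTACGT",   # 3 diffs from a1
            b2 = "ACTTACGAACGTACTTACGA")   # 1 diff from b1
  meta <- data.frame(specimen_id = names(seqs),
                     species_label = c("sp_a", "sp_a", "sp_b", "sp_b"),
                     stringsAsFactors = FALSE)
  build_dataset(barcode_alignment(seqs), meta)
}
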