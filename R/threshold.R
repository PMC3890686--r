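# Data-driven identification threshold: Gaussian kernel density of all
# pairwise distances, then local minima of the curve. The first (smallest)
# interior minimum is the proposed threshold -- on barcode-like data it is
# the dip between the intraspecific and interspecific distance modes.

#' Kernel density of pairwise distances
#'
#' Gaussian kernel, rule-of-thumb bandwidth
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)` (with `sd` as fallback when the IQR
#' is zero), evaluated exactly on 512 equally spaced points spanning
#' `[min - 3*bw, max + 3*bw]`. Exact evaluation (no FFT binning) keeps the
#' curve strictly positive and smooth, so the strict local-minimum rule
#' below is well defined even in deep valleys.
#'
#' @param values numeric vector of pairwise distances (at least 2, not all
#'   identical).
#' @return A `density_curve`: list with `grid` (512 points), `density`,
#'   `bandwidth`, `n`.
#' @export
distance_density <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop_barcodegap("precondition", "need at least 2 distance values")
  s <- stats::sd(values)
  if (s == 0) {
    stop_barcodegap("zero_bandwidth", "all distance values are identical; no density scale")
  }
  iqr <- stats::IQR(values)
  spread <- if (iqr > 0) min(s, iqr / 1.34) else s
  bw <- 0.9 * spread * n^(-1 / 5)
  grid <- seq(min(values) - 3 * bw, max(values) + 3 * bw, length.out = 512L)
  # exact KDE: average of Gaussian kernels at each grid point
  dens <- rowSums(stats::dnorm(outer(grid, values, "-"), sd = bw)) / n
  structure(list(grid = grid, density = dens, bandwidth = bw, n = n),
            class = "density_curve")
}

#' Local minima of a density curve
#'
#' Interior grid points whose density is strictly lower than both
#' neighbours. The selected threshold is the first (smallest-distance)
#' minimum; all minima are returned so the choice can be overridden. With
#' `plateau_ok = TRUE`, a flat valley (a run of equal values lower than
#' both flanks) also counts, represented by its leftmost point.
#'
#' @param curve a `density_curve`.
#' @param plateau_ok tolerate flat valleys (default `FALSE`: strict only).
#' @return A `threshold_result`: list with `minima` (ascending distances),
#'   `selected` (first minimum, `NA` if none), `bandwidth`,
#'   `selection_rule`.
#' @export
local_minima <- function(curve, plateau_ok = FALSE) {
  y <- curve$density
  g <- curve$grid
  m <- length(y)
  is_min <- logical(m)
  if (plateau_ok) {
    # collapse runs of equal values, then compare run to flanking runs
    r <- rle(y)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- length(r$values)
    if (k >= 3L) {
      for (q in 2:(k - 1L)) {
        if (r$values[q] < r$values[q - 1L] && r$values[q] < r$values[q + 1L]) {
          is_min[starts[q]] <- TRUE
        }
      }
    }
  } else if (m >= 3L) {
    core <- y[2:(m - 1L)]
    is_min[2:(m - 1L)] <- core < y[1:(m - 2L)] & core < y[3:m]
  }
  minima <- g[is_min]
  structure(list(minima = minima,
                 selected = if (length(minima)) minima[1] else NA_real_,
                 bandwidth = curve$bandwidth,
                 selection_rule = "first_local_minimum"),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (length(x$minima) == 0L) {
    cat("threshold_result: no local minima found (selected = NA)\n")
  } else {
    cat(sprintf("threshold_result: selected = %.4f (%s) of %d minima: %s\n",
                x$selected, x$selection_rule, length(x$minima),
                paste(sprintf("%.4f", x$minima), collapse = ", ")))
  }
  invisible(x)
}

#' Optimise the identification threshold from a distance matrix
#'
#' Pools the lower-triangle pairwise distances, estimates their density
#' ([distance_density()]) and selects the first local minimum
#' ([local_minima()]).
#'
#' @param dm a `k2p_dist` with at least 3 specimens.
#' @param plateau_ok passed to [local_minima()].
#' @return A `threshold_result`, with the `density_curve` attached as
#'   element `curve`.
#' @export
optimise_threshold <- function(dm, plateau_ok = FALSE) {
  if (length(dm$ids) < 3L) {
    stop_barcodegap("precondition", "threshold optimisation needs at least 3 specimens")
  }
  curve <- distance_density(pairwise_values(dm))
  res <- local_minima(curve, plateau_ok = plateau_ok)
  res$curve <- curve
  res
}
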