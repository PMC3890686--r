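# Internal helpers shared across modules.

# Classed error so callers/tests can dispatch on failure category.
stop_barcodegap <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0(class, "_error"), "barcodegap_error")))
}

#' Round half away from zero
#'
#' Percentages in identification summaries are printed to two decimals with
#' the conventional half-up rule (`round()` in R rounds half to even, which
#' would print 0.125 as 0.12 rather than 0.13).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Collapse a character vector for error messages.
.fmt_ids <- function(ids, max = 10) {
  if (length(ids) > max) {
    paste0(paste(ids[seq_len(max)], collapse = ", "), ", ... (", length(ids), " total)")
  } else {
    paste(ids, collapse = ", ")
  }
}
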