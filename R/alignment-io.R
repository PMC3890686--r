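# Reading, validating and joining aligned barcode data.
#
# The alignment container is a plain character matrix (specimens x columns,
# upper case, one IUPAC symbol per cell) with class "barcode_alignment".
# Columns are 0-based nowhere: internally we index with R's 1-based columns
# but all user-facing positions are reported 1-based.

# Alphabet accepted in aligned barcode sequences. 'U' is normalised to 'T'
# on read; everything is upper-cased.
BARCODE_ALPHABET <- c("A", "C", "G", "T", "-", "N",
                      "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a validated barcode alignment
#'
#' @param seqs named list or named character vector of aligned sequences
#'   (strings), or a character matrix with one row per specimen.
#' @return A `barcode_alignment`: character matrix, rownames = specimen IDs.
#' @export
barcode_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    ids <- rownames(seqs)
    mat <- seqs
  } else {
    ids <- names(seqs)
    chars <- lapply(seqs, function(s) {
      if (length(s) == 1L) strsplit(s, "")[[1]] else as.character(s)
    })
    lens <- lengths(chars)
    if (length(unique(lens)) > 1L) {
      modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
      bad <- ids[lens != modal]
      stop_barcodegap("alignment",
        "sequences are not aligned: length differs from %d bp for: %s",
        modal, .fmt_ids(bad))
    }
    mat <- do.call(rbind, chars)
    rownames(mat) <- ids
  }
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop_barcodegap("alignment", "every sequence must carry a non-empty specimen ID")
  }
  if (anyDuplicated(ids)) {
    stop_barcodegap("alignment", "duplicate specimen IDs: %s",
                    .fmt_ids(unique(ids[duplicated(ids)])))
  }
  if (nrow(mat) < 2L) stop_barcodegap("alignment", "an alignment needs at least 2 sequences")
  if (ncol(mat) < 1L) stop_barcodegap("alignment", "alignment has zero columns")
  mat <- toupper(mat)
  mat[mat == "U"] <- "T"
  bad <- which(!(mat %in% BARCODE_ALPHABET))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(mat)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(mat)) + 1L
    stop_barcodegap("alphabet",
      "illegal character '%s' in sequence '%s' at position %d (%d illegal site(s) in total)",
      mat[bad[1]], rownames(mat)[i], j, length(bad))
  }
  structure(mat, class = "barcode_alignment")
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat(sprintf("barcode_alignment: %d sequences x %d bp\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read an aligned multi-FASTA file
#'
#' The specimen ID is the first whitespace-delimited token of each header;
#' the remainder of the header is ignored. Sequences are upper-cased and `U`
#' is mapped to `T`. Unequal sequence lengths or characters outside the
#' IUPAC nucleotide alphabet (plus `-` and `N`) are errors.
#'
#' @param path path to a FASTA file.
#' @return A [barcode_alignment()].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop_barcodegap("io", "file not found: %s", path)
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = FALSE,
                             forceDNAtolower = FALSE, whole.header = FALSE)
  if (length(recs) == 0L) stop_barcodegap("io", "no FASTA records in %s", path)
  seqs <- lapply(recs, as.character)
  names(seqs) <- names(recs)
  barcode_alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param alignment a [barcode_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  seqinr::write.fasta(
    sequences = lapply(seq_len(nrow(alignment)), function(i) alignment[i, ]),
    names = rownames(alignment), file.out = path, nbchar = 80)
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Accepts a tab- or comma-separated table with a header. Required columns:
#' `specimen_id`, `species_label`; optional: `locality`, `outgroup`
#' (logical; outgroup specimens are excluded from distance-based analyses
#' by [partition_distances()] and the pipeline).
#'
#' @param path path to the table; the separator is sniffed from the header
#'   line (tab wins over comma).
#' @return data.frame with one row per specimen.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop_barcodegap("io", "file not found: %s", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop_barcodegap("schema", "metadata table %s is empty", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  validate_metadata(tab)
}

# Shared validation for metadata frames (read or constructed).
validate_metadata <- function(tab) {
  need <- c("specimen_id", "species_label")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop_barcodegap("schema", "metadata is missing required column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0L) stop_barcodegap("schema", "metadata table has no rows")
  tab$specimen_id <- as.character(tab$specimen_id)
  tab$species_label <- as.character(tab$species_label)
  if (any(!nzchar(tab$specimen_id))) stop_barcodegap("schema", "empty specimen_id")
  if (any(is.na(tab$species_label) | !nzchar(tab$species_label))) {
    stop_barcodegap("schema", "every specimen needs a non-empty species_label")
  }
  if (anyDuplicated(tab$specimen_id)) {
    stop_barcodegap("uniqueness", "duplicate specimen_id(s): %s",
                    .fmt_ids(unique(tab$specimen_id[duplicated(tab$specimen_id)])))
  }
  if (!is.null(tab$outgroup)) tab$outgroup <- as.logical(tab$outgroup)
  tab
}

#' Join an alignment and metadata into an analysis-ready dataset
#'
#' The specimen IDs of the two inputs must agree exactly; any ID present on
#' only one side is reported in the error. Metadata rows are reordered to
#' match the alignment.
#'
#' @param alignment a [barcode_alignment()].
#' @param metadata data.frame as returned by [read_metadata()].
#' @return A `barcode_dataset`: list with elements `alignment` and `metadata`.
#' @export
build_dataset <- function(alignment, metadata) {
  metadata <- validate_metadata(metadata)
  a_ids <- rownames(alignment)
  m_ids <- metadata$specimen_id
  only_a <- setdiff(a_ids, m_ids)
  only_m <- setdiff(m_ids, a_ids)
  if (length(only_a) || length(only_m)) {
    stop_barcodegap("join",
      "alignment and metadata IDs do not match; alignment-only: [%s]; metadata-only: [%s]",
      .fmt_ids(only_a), .fmt_ids(only_m))
  }
  metadata <- metadata[match(a_ids, m_ids), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(alignment = alignment, metadata = metadata),
            class = "barcode_dataset")
}

#' @export
print.barcode_dataset <- function(x, ...) {
  cat(sprintf("barcode_dataset: %d specimens, %d species, %d bp\n",
              nrow(x$alignment), length(unique(x$metadata$species_label)),
              ncol(x$alignment)))
  invisible(x)
}

#' Species labels of a dataset, in alignment order
#' @param dataset a `barcode_dataset`.
#' @return named character vector (names = specimen IDs).
#' @export
species_labels <- function(dataset) {
  stats::setNames(dataset$metadata$species_label, dataset$metadata$specimen_id)
}

#' Nucleotide base composition of an alignment
#'
#' Proportions of A, C, G and T over the unambiguous bases only; gaps, `N`
#' and IUPAC ambiguity codes enter neither numerator nor denominator.
#'
#' @param alignment a [barcode_alignment()], character matrix, or a plain
#'   character string / vector of residues.
#' @return named numeric vector `c(A=, C=, G=, T=)` summing to 1.
#' @export
base_composition <- function(alignment) {
  if (!is.matrix(alignment) && is.character(alignment) && any(nchar(alignment) > 1L)) {
    alignment <- unlist(strsplit(alignment, ""), use.names = FALSE)
  }
  alignment <- toupper(alignment)
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(alignment == b), numeric(1))
  tot <- sum(counts)
  if (tot == 0) {
    stop_barcodegap("degenerate_input",
                    "alignment contains no unambiguous A/C/G/T bases")
  }
  counts / tot
}
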