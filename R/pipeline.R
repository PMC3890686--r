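# End-to-end orchestration: (simulate | load) -> distances -> gap ->
# threshold -> identification -> MOTUs, with every stage's machine-readable
# output written under one directory and a manifest describing the run.

#' Pipeline configuration
#'
#' Exactly one of `fasta`+`metadata` (paths to an aligned FASTA and a
#' specimen table) or `sim` (a [simulation_config()]) must be supplied.
#' Thresholds may be fixed numbers or the string `"optimised"`, resolved
#' by [optimise_threshold()] before the identification and MOTU stages.
#'
#' @param out_dir output directory (created if needed).
#' @param fasta,metadata input file paths, or `NULL`.
#' @param sim a [simulation_config()], or `NULL`.
#' @param bcm_threshold best-close-match threshold (number or
#'   `"optimised"`).
#' @param tid_threshold fixed-radius identification threshold (default
#'   `0.01`).
#' @param motu_threshold MOTU linking threshold (number or `"optimised"`).
#' @param write_newick also write the single-linkage dendrogram.
#' @param precision decimals used in rounded report tables (default 3).
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, fasta = NULL, metadata = NULL, sim = NULL,
                            bcm_threshold = "optimised", tid_threshold = 0.01,
                            motu_threshold = "optimised",
                            write_newick = TRUE, precision = 3L) {
  have_files <- !is.null(fasta) || !is.null(metadata)
  have_sim <- !is.null(sim)
  if (have_files == have_sim) {
    stop_barcodegap("validation",
      "supply exactly one input source: fasta+metadata paths, or a simulation config")
  }
  if (have_files && (is.null(fasta) || is.null(metadata))) {
    stop_barcodegap("validation", "both fasta and metadata paths are required")
  }
  chk <- function(x, name) {
    if (is.numeric(x)) {
      if (x <= 0) stop_barcodegap("validation", "%s must be positive when fixed", name)
    } else if (!identical(x, "optimised")) {
      stop_barcodegap("validation", "%s must be a positive number or \"optimised\"", name)
    }
    x
  }
  structure(list(out_dir = out_dir, fasta = fasta, metadata = metadata, sim = sim,
                 bcm_threshold = chk(bcm_threshold, "bcm_threshold"),
                 tid_threshold = chk(tid_threshold, "tid_threshold"),
                 motu_threshold = chk(motu_threshold, "motu_threshold"),
                 write_newick = isTRUE(write_newick),
                 precision = as.integer(precision)),
            class = "pipeline_config")
}

#' Run the full barcoding analysis pipeline
#'
#' Stages, in order: input (load or simulate), K2P distance matrix,
#' barcode-gap assessment, threshold optimisation, leave-one-out
#' identification, MOTU delimitation + congruence. All artifacts are
#' written under `config$out_dir`; the returned manifest lists them and
#' any warnings (no density minimum, singleton species, saturated pairs).
#' When the threshold optimiser finds no minimum, identification and MOTU
#' delimitation fall back to the 1% default with a prominent warning.
#'
#' @param config a [pipeline_config()].
#' @return A `run_manifest`: list with `version`, `config`, `files`,
#'   `warnings`, `results` (in-memory stage results) and `status`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_barcodegap("validation", "config must come from pipeline_config()")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(version = as.character(utils::packageVersion("barcodegap")),
                   config = config, files = character(0), warnings = character(0),
                   results = list(), status = "running")
  note <- function(msg) {
    message("[barcodegap] ", msg)
    manifest$warnings <<- c(manifest$warnings, msg)
  }
  out <- function(name) file.path(config$out_dir, name)
  reg <- function(path) manifest$files <<- c(manifest$files, path)

  # -- input stage ----------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- simulate_dataset(config$sim)
    dataset <- sim$dataset
    manifest$results$sim <- sim
    write_alignment(dataset$alignment, out("alignment.fasta")); reg(out("alignment.fasta"))
    utils::write.table(dataset$metadata, out("metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE); reg(out("metadata.tsv"))
    write_ground_truth(sim, out("ground_truth.json")); reg(out("ground_truth.json"))
  } else {
    dataset <- build_dataset(read_alignment(config$fasta), read_metadata(config$metadata))
  }
  counts <- table(dataset$metadata$species_label)
  if (any(counts == 1L)) {
    note(sprintf("singleton species (no intraspecific distances): %s",
                 paste(names(counts)[counts == 1L], collapse = ", ")))
  }

  # -- distances ------------------------------------------------------
  dm <- withCallingHandlers(
    k2p_matrix(dataset, on_saturation = "na"),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  manifest$results$dm <- dm
  write_distance_matrix(dm, out("k2p_distances.tsv")); reg(out("k2p_distances.tsv"))

  # -- barcode gap ----------------------------------------------------
  part <- partition_distances(dm, dataset)
  gap <- gap_summary(part)
  manifest$results$gap <- gap
  jsonlite::write_json(unclass(gap), out("gap_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  reg(out("gap_summary.json"))
  gaps <- specimen_gap_table(dm, dataset)
  manifest$results$gap_table <- gaps
  utils::write.table(gaps, out("specimen_gap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE); reg(out("specimen_gap.tsv"))

  # -- threshold ------------------------------------------------------
  thr <- optimise_threshold(dm)
  manifest$results$threshold <- thr
  jsonlite::write_json(list(bandwidth = thr$bandwidth, minima = thr$minima,
                            selected = thr$selected,
                            selection_rule = thr$selection_rule),
                       out("threshold.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  reg(out("threshold.json"))
  utils::write.table(data.frame(distance = thr$curve$grid, density = thr$curve$density),
                     out("density_curve.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE); reg(out("density_curve.tsv"))
  if (is.na(thr$selected)) {
    note("no local density minimum found; falling back to the 1% default threshold")
  }
  optimised <- if (is.na(thr$selected)) 0.01 else thr$selected
  resolve <- function(x) if (identical(x, "optimised")) optimised else x

  # -- identification -------------------------------------------------
  ident <- evaluate_all(dataset, dm,
                        bcm_threshold = resolve(config$bcm_threshold),
                        tid_threshold = resolve(config$tid_threshold))
  manifest$results$identification <- ident
  utils::write.table(ident$outcomes, out("identification_outcomes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE); reg(out("identification_outcomes.tsv"))
  utils::write.table(ident$summary, out("identification_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE); reg(out("identification_summary.tsv"))
  jsonlite::write_json(list(thresholds = as.list(ident$thresholds),
                            summary = ident$summary),
                       out("identification_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  reg(out("identification_summary.json"))

  # -- MOTUs ----------------------------------------------------------
  motus <- delimit_motus(dm, resolve(config$motu_threshold))
  cong <- congruence_report(motus, dataset)
  manifest$results$motus <- motus
  manifest$results$congruence <- cong
  utils::write.table(data.frame(specimen_id = names(motus$assignments),
                                motu_id = unname(motus$assignments)),
                     out("motu_assignments.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE); reg(out("motu_assignments.tsv"))
  utils::write.table(cong$composition, out("motu_composition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE); reg(out("motu_composition.tsv"))
  utils::write.table(cong$mismatches, out("motu_mismatches.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE); reg(out("motu_mismatches.tsv"))
  if (config$write_newick) {
    writeLines(linkage_to_newick(dm), out("single_linkage.nwk"))
    reg(out("single_linkage.nwk"))
  }

  manifest$status <- "ok"
  empty <- manifest$files[!file.exists(manifest$files) | file.size(manifest$files) == 0]
  if (length(empty)) {
    manifest$status <- "error"
    note(sprintf("missing/empty outputs: %s", .fmt_ids(empty)))
  }
  manifest$files <- c(manifest$files, out("manifest.json"))
  manifest <- structure(manifest, class = "run_manifest")
  jsonlite::write_json(list(version = manifest$version, status = manifest$status,
                            files = basename(manifest$files),
                            warnings = manifest$warnings),
                       out("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Render a human-readable summary of a pipeline run
#'
#' Deterministic text mirroring the narrative order of a barcoding study:
#' gap summary, threshold, identification table (criterion x outcome with
#' n and %), MOTU composition and label mismatches.
#'
#' @param manifest a `run_manifest` from [run_pipeline()].
#' @return character vector of report lines (also printable with `cat`).
#' @export
render_summary <- function(manifest) {
  if (!identical(manifest$status, "ok")) {
    return(c("PIPELINE FAILED", paste(" warning:", manifest$warnings)))
  }
  p <- manifest$config$precision
  fmt <- function(x) formatC(x, digits = p, format = "f")
  g <- manifest$results$gap
  thr <- manifest$results$threshold
  ident <- manifest$results$identification
  cong <- manifest$results$congruence
  lines <- c(
    "== Barcode gap ==",
    sprintf("intraspecific: median %s, range %s-%s (n = %d pairs)",
            fmt(g$intra_median), fmt(g$intra_min), fmt(g$intra_max), g$n_intra),
    sprintf("interspecific: median %s, range %s-%s (n = %d pairs)",
            fmt(g$inter_median), fmt(g$inter_min), fmt(g$inter_max), g$n_inter),
    sprintf("Wilcoxon rank-sum: two-sided p = %.3g (inter > intra: p = %.3g; %s)",
            g$wilcoxon_p, g$wilcoxon_p_greater,
            if (g$wilcoxon_exact) "exact" else "normal approximation"),
    "note: pairwise distances are non-independent; p-values are descriptive",
    sprintf("gap by medians: %s | gap by extremes: %s",
            g$gap_by_median, g$gap_by_extremes),
    "",
    "== Threshold ==",
    if (is.na(thr$selected)) {
      "no local density minimum; 1% fallback threshold in use"
    } else {
      sprintf("selected threshold d = %s (%s; bandwidth %.4g, %d minima)",
              fmt(thr$selected), thr$selection_rule, thr$bandwidth,
              length(thr$minima))
    },
    "",
    "== Identification (leave-one-out) ==")
  for (cr in unique(ident$summary$criterion)) {
    sub <- ident$summary[ident$summary$criterion == cr, ]
    lines <- c(lines, sprintf("%-16s %s", cr,
      paste(sprintf("%s %d (%.2f%%)", sub$outcome, sub$n, sub$pct), collapse = " | ")))
  }
  lines <- c(lines, "", "== MOTUs ==",
             sprintf("%d MOTUs at threshold %s", length(manifest$results$motus$motus),
                     fmt(manifest$results$motus$threshold)))
  comp <- cong$composition
  for (mid in unique(comp$motu_id)) {
    sub <- comp[comp$motu_id == mid, ]
    lines <- c(lines, sprintf("%s: %s", mid,
      paste(sprintf("%s (%d)", sub$species_label, sub$n), collapse = ", ")))
  }
  lines <- c(lines,
             sprintf("label/MOTU mismatches: %d", nrow(cong$mismatches)))
  if (nrow(cong$mismatches)) {
    lines <- c(lines, sprintf("  %s labeled %s sits in %s (majority %s)",
                              cong$mismatches$specimen_id,
                              cong$mismatches$species_label,
                              cong$mismatches$motu_id,
                              cong$mismatches$majority_species))
  }
  if (length(manifest$warnings)) {
    lines <- c(lines, "", "== Warnings ==", paste(" -", manifest$warnings))
  }
  lines
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: status %s, %d files, %d warning(s)\n",
              x$status, length(x$files), length(x$warnings)))
  invisible(x)
}
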