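## End-to-end workflow: scan -> histograms -> sense -> anchor -> cluster ->
## call, with per-stage accounting.

#' Run the full expansion-detection pipeline
#'
#' Scans case and control read pairs, senses repeat units whose
#' full-read-length occurrences are abundant in the case but absent from all
#' controls, anchors the case's STR-filled reads through their mates,
#' clusters the anchors and calls significantly expanded loci.
#'
#' @param case_pairs Case read pairs: a `data.frame` (`pair_id`, `seq1`,
#'   `seq2`) or a length-2 character vector of FASTQ paths.
#' @param control_pairs List of control samples in the same formats.
#' @param reference Reference for builtin mate anchoring: named character
#'   vector or FASTA path.  Required unless `mode = "sam"`.
#' @param alignments For `mode = "sam"`: mate alignments from
#'   [read_mate_alignments()].
#' @param mode Anchoring mode, `"builtin"` (exact unique match against
#'   `reference`) or `"sam"` (external aligner output).
#' @param read_length Uniform read length; inferred from the case reads when
#'   `NULL`.
#' @param unit_range Unit lengths scanned, see [scan_reads()].
#' @param min_occ Minimum occurrence length for anchoring (default 50).
#' @param cluster_window Anchor clustering window (default 300, the average
#'   insert size).
#' @param alpha,n_windows Bonferroni correction: the per-locus significance
#'   threshold is `alpha / n_windows` (default 0.05 / 1e7 = 5e-9).
#' @param min_full_reads Sensing threshold, see [sense_expanded_units()].
#' @param min_anchors Minimum cluster size for a call (default 5).
#' @param mapq_min Minimum MAPQ for `sam`-mode anchors.
#' @param sd_type Grubbs standard-deviation convention.
#' @param out_dir If not `NULL`, write occurrence TSVs, histogram TSVs, a
#'   BED of calls and a run report under this directory.
#' @return Object of class `str_scan_result`: list with `histograms`
#'   (case + controls), `sensed` (unit table), `clusters`, `calls`
#'   (`str_calls`) and `report` (per-stage counts and parameters).
#' @export
run_pipeline <- function(case_pairs, control_pairs = list(),
                         reference = NULL, alignments = NULL,
                         mode = c("builtin", "sam"), read_length = NULL,
                         unit_range = c(2L, 6L), min_occ = 50L,
                         cluster_window = 300L, alpha = 0.05,
                         n_windows = 1e7, min_full_reads = 10L,
                         min_anchors = 5L, mapq_min = 20L,
                         sd_type = "population", out_dir = NULL) {
  mode <- match.arg(mode)
  load_pairs <- function(x) {
    if (is.character(x) && length(x) == 2L) read_fastq_pairs(x[1], x[2])
    else x
  }
  case_pairs <- load_pairs(case_pairs)
  control_pairs <- lapply(control_pairs, load_pairs)
  stopifnot(is.data.frame(case_pairs))
  if (is.null(read_length)) {
    read_length <- if (nrow(case_pairs)) nchar(case_pairs$seq1[1]) else 0L
  }
  read_length <- as.integer(read_length)

  scan_sample <- function(pairs, label) {
    if (!nrow(pairs)) {
      occ <- scan_reads(character(0))
    } else {
      occ <- scan_reads(c(pairs$seq1, pairs$seq2),
                        read_ids = c(paste0(pairs$pair_id, "/1"),
                                     paste0(pairs$pair_id, "/2")),
                        unit_range = unit_range, flanks = FALSE)
    }
    list(occ = occ,
         hist = str_histogram(occ, read_length = max(read_length, 2L),
                              sample_id = label))
  }

  case_scan <- scan_sample(case_pairs, "case")
  control_labels <- if (length(control_pairs))
    paste0("control", seq_along(control_pairs)) else character(0)
  control_scans <- Map(scan_sample, control_pairs, control_labels)
  control_hists <- lapply(control_scans, `[[`, "hist")

  sensed <- if (nrow(case_pairs)) {
    if (length(control_hists))
      sense_expanded_units(case_scan$hist, control_hists,
                           min_full_reads = min_full_reads)
    else
      suppressWarnings(sense_expanded_units(case_scan$hist, list(),
                                            min_full_reads = min_full_reads))
  } else {
    data.frame(unit = character(0), case_full = integer(0))
  }

  report <- list(
    parameters = list(read_length = read_length, unit_range = unit_range,
                      min_occ = min_occ, cluster_window = cluster_window,
                      alpha = alpha, n_windows = n_windows,
                      min_full_reads = min_full_reads,
                      min_anchors = min_anchors, mapq_min = mapq_min,
                      mode = mode),
    n_case_pairs = nrow(case_pairs),
    n_control_pairs = vapply(control_pairs, nrow, integer(1)),
    n_case_occurrences = nrow(case_scan$occ),
    n_sensed_units = nrow(sensed))

  anchors <- data.frame()
  control_anchors <- list()
  clusters <- list()
  if (nrow(sensed)) {
    cand <- select_anchor_pairs(case_pairs, occ = case_scan$occ,
                                min_len = min_occ, units = sensed$unit)
    report$n_candidate_pairs <- nrow(cand)
    report$n_both_repetitive <- attr(cand, "n_both_repetitive")
    anchors <- anchor_mates(cand, mode = mode, reference = reference,
                            alignments = alignments, mapq_min = mapq_min)
    report$n_anchors <- nrow(anchors)
    report$n_anchor_dropped <- attr(anchors, "n_dropped")
    control_anchors <- lapply(seq_along(control_scans), function(i) {
      cc <- select_anchor_pairs(control_pairs[[i]],
                                occ = control_scans[[i]]$occ,
                                min_len = min_occ, units = sensed$unit)
      anchor_mates(cc, mode = "builtin", reference = reference)
    })
    clusters <- cluster_anchors(anchors, window = cluster_window,
                                read_length = read_length)
    report$n_clusters <- length(clusters)
  } else {
    report$n_candidate_pairs <- 0L
    report$n_both_repetitive <- 0L
    report$n_anchors <- 0L
    report$n_anchor_dropped <- 0L
    report$n_clusters <- 0L
  }

  calls <- call_expansions(clusters, control_anchors = control_anchors,
                           control_histograms = control_hists,
                           alpha = alpha, n_windows = n_windows,
                           min_anchors = min_anchors, l_min = min_occ,
                           read_length = read_length,
                           window = cluster_window, sd_type = sd_type)
  report$n_significant <- sum(calls$significant)

  res <- structure(list(case_histogram = case_scan$hist,
                        control_histograms = control_hists,
                        sensed = sensed, anchors = anchors,
                        clusters = clusters, calls = calls,
                        report = report),
                   class = "str_scan_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_occurrences_tsv(case_scan$occ,
                          file.path(out_dir, "case_occurrences.tsv"))
    write_histogram_tsv(case_scan$hist,
                        file.path(out_dir, "case_histogram.tsv"))
    for (i in seq_along(control_hists))
      write_histogram_tsv(control_hists[[i]],
                          file.path(out_dir,
                                    sprintf("control%d_histogram.tsv", i)))
    write_calls_bed(calls, file.path(out_dir, "calls.bed"))
    writeLines(format_report(res), file.path(out_dir, "run_report.txt"))
  }
  res
}

format_report <- function(x) {
  r <- x$report
  p <- r$parameters
  c(sprintf("strsense run report (read length %d, units %d-%d)",
            p$read_length, p$unit_range[1], p$unit_range[2]),
    sprintf("case pairs: %d (occurrences: %d)", r$n_case_pairs,
            r$n_case_occurrences),
    sprintf("control pairs: %s",
            paste(r$n_control_pairs, collapse = ", ")),
    sprintf("sensed units (> %d full-length reads, controls clean): %d",
            p$min_full_reads, r$n_sensed_units),
    sprintf("candidate pairs: %d (both-end repetitive dropped: %d)",
            r$n_candidate_pairs, r$n_both_repetitive),
    sprintf("unique anchors: %d (dropped: %d)", r$n_anchors,
            r$n_anchor_dropped),
    sprintf("clusters: %d; significant calls (p < %g, >= %d anchors): %d",
            r$n_clusters, p$alpha / p$n_windows, p$min_anchors,
            r$n_significant))
}

#' @export
print.str_scan_result <- function(x, ...) {
  writeLines(format_report(x))
  if (nrow(x$sensed)) {
    cat("sensed units:\n")
    print(x$sensed, row.names = FALSE)
  }
  sig <- x$calls[x$calls$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("significant expansions (1-based coordinates):\n")
    show <- as.data.frame(sig)
    show$start <- show$start + 1L
    print(show[, c("chrom", "start", "end", "unit", "n_anchors", "f_top",
                   "t_score", "p_value")], row.names = FALSE)
  }
  invisible(x)
}
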