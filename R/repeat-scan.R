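## Per-read STR scanning: maximal exact repetitions, greedy approximate
## extension, and same-unit overlap pruning.

#' Enumerate maximal exact repetitions in a sequence
#'
#' A repetition is a string of the form `x^k x'` with `k >= 2` and `x'` a
#' proper prefix of `x`; it is maximal if it is not a proper substring of a
#' repetition with the same unit.  Every maximal repetition is reported once
#' with its minimum (primitive) unit.  Non-ACGT characters split the sequence
#' into blocks scanned independently.
#'
#' @param seq A single DNA string (length >= 2 after case folding).
#' @param method `"runs"` (default, period-anchor enumeration, expected
#'   linearithmic on read-like input) or `"brute"` (direct-from-definition
#'   cubic enumeration, intended as a testing oracle).
#' @return A `data.frame` with 0-based half-open columns `start`, `end` and
#'   the primitive `unit`, sorted by `(start, end, unit)`.
#' @examples
#' maximal_repetitions("CAGCAGCA")  # one row: [0, 8), unit CAG
#' maximal_repetitions("ACGT")      # empty
#' @export
maximal_repetitions <- function(seq, method = c("runs", "brute")) {
  method <- match.arg(method)
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  if (nchar(seq) < 2L)
    return(data.frame(start = integer(0), end = integer(0),
                      unit = character(0), stringsAsFactors = FALSE))
  cpp_maximal_repetitions(seq, method == "brute")
}

#' Extend an exact repetition into an approximate STR occurrence
#'
#' Greedy single-edit extension: at each boundary a mismatch, deletion or
#' insertion against the periodic continuation of the unit is accepted only
#' if it is followed (outward) by an exact periodic match of at least
#' `|unit|` bases; extension stops when no single edit qualifies or the read
#' (or an ACGT block) boundary is reached.  The left boundary is extended to
#' exhaustion first, then the right; when several edits qualify, preference
#' is mismatch > deletion > insertion.
#'
#' @param seq A single DNA string containing the seed repetition.
#' @param start,end 0-based half-open span of the exact seed repetition.
#' @param unit Unit of the seed; `seq[start, end)` must equal the unit
#'   repeated (with a final proper prefix allowed).
#' @return A one-row `data.frame` with `start`, `end`, `length`,
#'   `n_mismatch`, `n_insertion`, `n_deletion`, `n_mutations`.
#' @export
extend_approximate <- function(seq, start, end, unit) {
  stopifnot(is.character(seq), length(seq) == 1L)
  e <- cpp_extend(seq, as.integer(start), as.integer(end), unit)
  data.frame(start = e$start, end = e$end, length = e$end - e$start,
             n_mismatch = e$n_mismatch, n_insertion = e$n_insertion,
             n_deletion = e$n_deletion, n_mutations = e$n_mutations)
}

#' Prune overlapping same-unit occurrences within one read
#'
#' Among occurrences with the same canonical unit that overlap, only the
#' longest survives; exact length ties are resolved in favour of the smallest
#' start.  Occurrences of different units may still overlap.
#'
#' @param occ Occurrence `data.frame` from one read with at least columns
#'   `unit`, `start`, `end`.
#' @return The surviving rows, sorted by `(start, end, unit)`.
#' @export
prune_overlaps <- function(occ) {
  stopifnot(is.data.frame(occ), all(c("unit", "start", "end") %in% names(occ)))
  if (nrow(occ) < 2L) return(occ)
  len <- occ$end - occ$start
  ord <- order(-len, occ$start, occ$unit)
  keep <- logical(nrow(occ))
  taken <- split(seq_len(0), character(0))
  for (i in ord) {
    iv <- taken[[occ$unit[i]]]
    clash <- FALSE
    if (!is.null(iv) && length(iv)) {
      clash <- any(occ$start[i] < occ$end[iv] & occ$start[iv] < occ$end[i])
    }
    if (!clash) {
      keep[i] <- TRUE
      taken[[occ$unit[i]]] <- c(iv, i)
    }
  }
  out <- occ[keep, , drop = FALSE]
  out[order(out$start, out$end, out$unit), , drop = FALSE]
}

#' Scan reads for approximate STR occurrences
#'
#' Composes the full per-read scan: maximal exact repetitions, unit-length
#' filtering, greedy single-edit extension, canonical-unit reduction (which
#' also removes reverse-complement redundancy) and same-unit overlap pruning.
#' Occurrences shorter than `min_length` (default: twice the unit length) are
#' dropped.
#'
#' @param seqs Character vector of read sequences.
#' @param read_ids Read identifiers; defaults to `names(seqs)` or the index.
#' @param unit_range Length-2 integer vector `(min, max)` of unit lengths to
#'   report.  The default `c(2, 6)` is the classical STR definition; raise
#'   the upper bound (e.g. to 10) to catch longer disease units.  Setting the
#'   minimum to 1 re-enables homopolymer runs.
#' @param min_length Minimum occurrence length in bases, or `NULL` for the
#'   per-unit default `2 * |unit|`.
#' @param flanks If `TRUE` (default), include the read substrings flanking
#'   each occurrence.
#' @return A `data.frame` with one row per surviving occurrence: `read_id`,
#'   canonical `unit`, `raw_unit` as observed, 0-based half-open `start`,
#'   `end`, `length`, edit counts and (optionally) `left_flank`,
#'   `right_flank`.
#' @examples
#' scan_reads(strrep("AC", 20))
#' @export
scan_reads <- function(seqs, read_ids = NULL, unit_range = c(2L, 6L),
                       min_length = NULL, flanks = TRUE) {
  stopifnot(is.character(seqs))
  unit_range <- as.integer(unit_range)
  stopifnot(length(unit_range) == 2L, unit_range[1] >= 1L,
            unit_range[2] >= unit_range[1])
  if (is.null(read_ids)) {
    read_ids <- if (!is.null(names(seqs))) names(seqs)
                else as.character(seq_along(seqs))
  }
  stopifnot(length(read_ids) == length(seqs))
  ml <- if (is.null(min_length)) 0L else as.integer(min_length)
  occ <- cpp_scan_reads(seqs, unit_range[1], unit_range[2], ml)
  out <- data.frame(read_id = read_ids[occ$read], unit = occ$unit,
                    raw_unit = occ$raw_unit, start = occ$start, end = occ$end,
                    length = occ$end - occ$start,
                    n_mismatch = occ$n_mismatch,
                    n_insertion = occ$n_insertion,
                    n_deletion = occ$n_deletion,
                    n_mutations = occ$n_mismatch + occ$n_insertion +
                      occ$n_deletion,
                    stringsAsFactors = FALSE)
  if (flanks) {
    seq_of <- seqs[occ$read]
    out$left_flank <- substr(seq_of, 1L, occ$start)
    out$right_flank <- substr(seq_of, occ$end + 1L, nchar(seq_of))
  }
  out
}

#' @rdname scan_reads
#' @param seq A single read sequence.
#' @export
scan_read <- function(seq, unit_range = c(2L, 6L), min_length = NULL,
                      flanks = TRUE) {
  scan_reads(seq, read_ids = "1", unit_range = unit_range,
             min_length = min_length, flanks = flanks)
}
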