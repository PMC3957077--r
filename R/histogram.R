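## Per-unit length-frequency histograms and case/control sensing.
##
## Each read contributes at most one count per unit: its longest occurrence
## of that unit.  A unit whose full-read-length occurrences are frequent in
## the case sample but absent from every control signals an expansion longer
## than the read length.

#' Build a per-unit STR length histogram for one sample
#'
#' Tallies, per canonical unit and occurrence length, the number of reads
#' whose longest occurrence of that unit has that length.
#'
#' @param occ Occurrence `data.frame` from [scan_reads()] (columns `read_id`,
#'   `unit`, `length`).
#' @param read_length Uniform read length of the sample, in bases.
#' @param sample_id Sample label.
#' @return An object of class `str_histogram`: a list with `sample_id`,
#'   `read_length` and a `counts` data.frame (`unit`, `length`, `count`).
#' @export
str_histogram <- function(occ, read_length, sample_id = "sample") {
  stopifnot(is.data.frame(occ))
  read_length <- as.integer(read_length)
  stopifnot(length(read_length) == 1L, read_length >= 2L)
  if (nrow(occ) && any(occ$length > read_length))
    stop("occurrence longer than read_length: histogram inconsistent")
  if (nrow(occ)) {
    dt <- data.table::data.table(read_id = occ$read_id, unit = occ$unit,
                                 length = occ$length)
    longest <- dt[, list(length = max(length)), by = c("read_id", "unit")]
    counts <- longest[, list(count = .N), by = c("unit", "length")]
    counts <- as.data.frame(counts[order(unit, length)])
  } else {
    counts <- data.frame(unit = character(0), length = integer(0),
                         count = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(sample_id = sample_id, read_length = read_length,
                 counts = counts),
            class = "str_histogram")
}

#' @export
print.str_histogram <- function(x, ...) {
  cat("STR length histogram: sample", x$sample_id,
      "| read length", x$read_length, "\n")
  cat(" ", nrow(x$counts), "(unit, length) bins,",
      length(unique(x$counts$unit)), "units,",
      sum(x$counts$count), "read-unit counts\n")
  full <- x$counts[x$counts$length == x$read_length, , drop = FALSE]
  if (nrow(full)) {
    full <- full[order(-full$count), , drop = FALSE]
    cat("  top full-read-length units:",
        paste0(head(full$unit, 5L), " (", head(full$count, 5L), ")",
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Merge STR histograms
#'
#' Summing counts bin-wise; associative and commutative, so samples can be
#' accumulated in shards.  All histograms must share the read length.
#'
#' @param ... `str_histogram` objects (or a single list of them).
#' @param sample_id Label for the merged histogram; defaults to the first
#'   input's label.
#' @return A merged `str_histogram`.
#' @export
merge_histograms <- function(..., sample_id = NULL) {
  hs <- list(...)
  if (length(hs) == 1L && !inherits(hs[[1]], "str_histogram")) hs <- hs[[1]]
  stopifnot(length(hs) >= 1L,
            all(vapply(hs, inherits, logical(1), "str_histogram")))
  rl <- unique(vapply(hs, function(h) h$read_length, integer(1)))
  if (length(rl) != 1L) stop("histograms have differing read lengths")
  counts <- data.table::rbindlist(lapply(hs, function(h) h$counts))
  merged <- counts[, list(count = sum(count)), by = c("unit", "length")]
  merged <- as.data.frame(merged[order(unit, length)])
  structure(list(sample_id = if (is.null(sample_id)) hs[[1]]$sample_id
                             else sample_id,
                 read_length = rl, counts = merged),
            class = "str_histogram")
}

full_length_counts <- function(h) {
  full <- h$counts[h$counts$length == h$read_length, , drop = FALSE]
  setNames(full$count, full$unit)
}

#' Sense repeat units expanded in the case sample
#'
#' Reports units with strictly more than `min_full_reads` full-read-length
#' occurrences in the case histogram and zero full-read-length occurrences in
#' every control histogram.  A full-length occurrence (one spanning the whole
#' read) is the signature of an expansion longer than the read.
#'
#' @param case `str_histogram` of the case sample.
#' @param controls List of control `str_histogram`s (may be empty, with a
#'   warning: case-only sensing).
#' @param min_full_reads Count threshold; a unit is reported only when the
#'   case count exceeds it strictly (default 10).
#' @param control_max_length If not `NULL`, relax the control-absence
#'   condition from "no full-length occurrence" to "no occurrence of at
#'   least `control_max_length` bases".
#' @return A `data.frame` (`unit`, `case_full`) sorted by descending case
#'   count.
#' @export
sense_expanded_units <- function(case, controls = list(),
                                 min_full_reads = 10L,
                                 control_max_length = NULL) {
  stopifnot(inherits(case, "str_histogram"),
            all(vapply(controls, inherits, logical(1), "str_histogram")))
  rl <- case$read_length
  if (length(controls) &&
      any(vapply(controls, function(h) h$read_length, integer(1)) != rl))
    stop("case and control histograms have differing read lengths")
  if (!length(controls))
    warning("no control histograms supplied: case-only sensing")
  cf <- full_length_counts(case)
  cf <- cf[cf > min_full_reads]
  if (!length(cf))
    return(data.frame(unit = character(0), case_full = integer(0),
                      stringsAsFactors = FALSE))
  thresh <- if (is.null(control_max_length)) rl
            else as.integer(control_max_length)
  ok <- vapply(names(cf), function(u) {
    !any(vapply(controls, function(h) {
      sub <- h$counts[h$counts$unit == u & h$counts$length >= thresh, ,
                      drop = FALSE]
      sum(sub$count) > 0L
    }, logical(1)))
  }, logical(1))
  cf <- cf[ok]
  cf <- sort(cf, decreasing = TRUE)
  data.frame(unit = names(cf), case_full = as.integer(cf),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare a unit's length distribution across samples
#'
#' @param unit Canonical repeat unit.
#' @param samples List of `str_histogram`s.
#' @return Long-format `data.frame` (`sample`, `length`, `count`), with an
#'   attribute `max_length` (named vector of the maximum observed length per
#'   sample that has the unit).
#' @export
compare_distributions <- function(unit, samples) {
  stopifnot(length(samples) >= 1L,
            all(vapply(samples, inherits, logical(1), "str_histogram")))
  rows <- lapply(samples, function(h) {
    sub <- h$counts[h$counts$unit == unit, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    data.frame(sample = h$sample_id, length = sub$length, count = sub$count,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample = character(0), length = integer(0),
                      count = integer(0), stringsAsFactors = FALSE)
  mx <- if (nrow(out)) tapply(out$length, out$sample, max) else integer(0)
  attr(out, "max_length") <- mx
  out
}
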