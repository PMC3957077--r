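## Locating candidate expansions: mate anchoring, clustering, and the
## Smirnov-Grubbs outlier call.
##
## A read filled wall-to-wall by an STR cannot be placed on its own, but its
## paired-end mate often maps to a unique position within one insert length
## of the repeat locus.  Anchors are clustered per unit within the average
## insert size; in each cluster the frequency distribution of occurrence
## lengths (50 bp .. read length) is tested for an excess of full-length
## occurrences.

#' Select anchorable read pairs
#'
#' A pair is a candidate when exactly one end carries an STR occurrence of at
#' least `min_len` bases (that end is the STR side); pairs repetitive on both
#' ends are unanchorable and dropped.
#'
#' @param pairs `data.frame` of read pairs with columns `pair_id`, `seq1`,
#'   `seq2`.
#' @param occ Occurrence table from [scan_reads()] run on both ends, with
#'   `read_id` of the form `"<pair_id>/1"` / `"<pair_id>/2"`.  If `NULL`,
#'   both ends are scanned here with `unit_range`.
#' @param min_len Minimum occurrence length designating the STR side
#'   (default 50).
#' @param unit_range Passed to [scan_reads()] when `occ` is `NULL`.
#' @param units Optional character vector restricting candidate units.
#' @return `data.frame` with one row per (pair, unit): `pair_id`, `unit`,
#'   `str_end` (1 or 2), `occ_length`, `mate_seq`, plus the STR-side read
#'   substrings outside the occurrence (`flank_left`, `flank_right`,
#'   possibly empty) used for flank-based direct placement.  The attribute
#'   `n_both_repetitive` counts dropped both-end-repetitive pairs.
#' @export
select_anchor_pairs <- function(pairs, occ = NULL, min_len = 50L,
                                unit_range = c(2L, 6L), units = NULL) {
  stopifnot(is.data.frame(pairs),
            all(c("pair_id", "seq1", "seq2") %in% names(pairs)))
  if (is.null(occ)) {
    seqs <- c(pairs$seq1, pairs$seq2)
    ids <- c(paste0(pairs$pair_id, "/1"), paste0(pairs$pair_id, "/2"))
    occ <- scan_reads(seqs, read_ids = ids, unit_range = unit_range,
                      flanks = FALSE)
  }
  long <- occ[occ$length >= min_len, , drop = FALSE]
  empty <- data.frame(pair_id = character(0), unit = character(0),
                      str_end = integer(0), occ_length = integer(0),
                      mate_seq = character(0), flank_left = character(0),
                      flank_right = character(0), stringsAsFactors = FALSE)
  if (!nrow(long)) {
    attr(empty, "n_both_repetitive") <- 0L
    return(empty)
  }
  m <- regmatches(long$read_id, regexec("^(.*)/([12])$", long$read_id))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("read ids must end in /1 or /2 to link mates (offending: ",
         long$read_id[which(bad)[1]], ")")
  long$pair_id <- vapply(m, `[`, character(1), 2L)
  long$str_end <- as.integer(vapply(m, `[`, character(1), 3L))
  if (!all(long$pair_id %in% pairs$pair_id))
    stop("occurrence references a pair absent from `pairs`: linkage error")
  # longest qualifying occurrence per (pair, end, unit)
  dt <- data.table::data.table(pair_id = long$pair_id, unit = long$unit,
                               str_end = long$str_end,
                               occ_length = long$length,
                               occ_start = long$start, occ_end = long$end)
  dt <- dt[order(-occ_length)]
  dt <- dt[, .SD[1L], by = c("pair_id", "unit", "str_end")]
  ends <- unique(dt[, c("pair_id", "str_end")])
  both <- ends[, list(n = .N), by = "pair_id"]
  both_ids <- both$pair_id[both$n > 1L]
  out <- dt[!dt$pair_id %in% both_ids]
  if (!is.null(units)) out <- out[out$unit %in% units]
  out <- as.data.frame(out)
  if (nrow(out)) {
    idx <- match(out$pair_id, pairs$pair_id)
    str_seq <- ifelse(out$str_end == 1L, pairs$seq1[idx], pairs$seq2[idx])
    out$mate_seq <- ifelse(out$str_end == 1L, pairs$seq2[idx],
                           pairs$seq1[idx])
    out$flank_left <- substr(str_seq, 1L, out$occ_start)
    out$flank_right <- substr(str_seq, out$occ_end + 1L, nchar(str_seq))
    out$occ_start <- NULL
    out$occ_end <- NULL
  } else {
    out <- empty
  }
  attr(out, "n_both_repetitive") <- length(both_ids)
  out
}

#' Anchor candidate pairs through their mates
#'
#' In `builtin` mode the anchor is found by exact search against both
#' strands of the supplied reference: if the STR-side read retains a flank
#' of at least `flank_min` bases that matches uniquely, the locus is placed
#' directly from the flank; otherwise the mate is searched, unique iff
#' exactly one hit exists.  In `sam` mode, alignments produced by an
#' external aligner (e.g. BWA-MEM) are consulted: an anchor is unique when
#' its mate is mapped, not multi-mapped (no secondary/supplementary record,
#' MAPQ > 0) and has `MAPQ >= mapq_min`.
#'
#' @param candidates Output of [select_anchor_pairs()].
#' @param mode `"builtin"` or `"sam"`.
#' @param reference For `builtin` mode: named character vector of reference
#'   sequences (or a FASTA path).
#' @param alignments For `sam` mode: output of [read_mate_alignments()].
#' @param mapq_min Minimum mapping quality for a unique anchor in `sam` mode.
#' @param flank_min Minimum STR-side flank length for direct placement in
#'   `builtin` mode (default 30); set above the read length to disable.
#' @return `data.frame` of unique anchors: `pair_id`, `unit`, `occ_length`,
#'   `mate_chrom`, `mate_start` (0-based), `mate_strand`, `mapq` and
#'   `source` (`"flank"` or `"mate"`).  The attribute `n_dropped` counts
#'   candidates without a unique anchor.
#' @export
anchor_mates <- function(candidates, mode = c("builtin", "sam"),
                         reference = NULL, alignments = NULL,
                         mapq_min = 20L, flank_min = 30L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(candidates))
  empty <- data.frame(pair_id = character(0), unit = character(0),
                      occ_length = integer(0), mate_chrom = character(0),
                      mate_start = integer(0), mate_strand = character(0),
                      mapq = integer(0), source = character(0),
                      stringsAsFactors = FALSE)
  attr(empty, "n_dropped") <- 0L
  if (!nrow(candidates)) return(empty)
  if (mode == "builtin") {
    if (is.null(reference)) stop("builtin mode requires a reference")
    if (length(reference) == 1L && is.null(names(reference)) &&
        file.exists(reference))
      reference <- read_fasta(reference)
    if (is.null(names(reference)))
      names(reference) <- paste0("seq", seq_along(reference))
    ref_set <- Biostrings::DNAStringSet(reference)
    hit_one <- function(query) {
      hits <- NULL
      n <- 0L
      pats <- c(`+` = query, `-` = dna_revcomp(query))
      for (chrom in names(reference)) {
        for (strand in c("+", "-")) {
          mp <- Biostrings::matchPattern(pats[[strand]],
                                         ref_set[[chrom]])
          k <- length(mp)
          if (k > 0L) {
            n <- n + k
            if (n > 1L) return(NULL)
            hits <- list(chrom = chrom,
                         start = BiocGenerics::start(mp)[1] - 1L,
                         strand = strand)
          }
        }
      }
      if (n == 1L) hits else NULL
    }
    has_flanks <- all(c("flank_left", "flank_right") %in% names(candidates))
    place_one <- function(i) {
      # flank-based direct placement first, mate anchoring as fallback
      if (has_flanks) {
        fl <- candidates$flank_left[i]
        fr <- candidates$flank_right[i]
        flank <- if (nchar(fl) >= nchar(fr)) fl else fr
        if (!is.na(flank) && nchar(flank) >= flank_min) {
          h <- hit_one(flank)
          if (!is.null(h)) return(c(h, list(source = "flank")))
        }
      }
      h <- hit_one(candidates$mate_seq[i])
      if (!is.null(h)) c(h, list(source = "mate")) else NULL
    }
    res <- lapply(seq_len(nrow(candidates)), place_one)
    ok <- !vapply(res, is.null, logical(1))
    out <- candidates[ok, c("pair_id", "unit", "occ_length"), drop = FALSE]
    out$mate_chrom <- vapply(res[ok], `[[`, character(1), "chrom")
    out$mate_start <- vapply(res[ok], `[[`, integer(1), "start")
    out$mate_strand <- vapply(res[ok], `[[`, character(1), "strand")
    out$mapq <- NA_integer_
    out$source <- vapply(res[ok], `[[`, character(1), "source")
  } else {
    if (is.null(alignments)) stop("sam mode requires `alignments`")
    mate_end <- 3L - candidates$str_end
    key <- paste0(candidates$pair_id, "/", mate_end)
    idx <- match(key, alignments$read_id)
    missing_aln <- is.na(idx)
    al <- alignments[idx, , drop = FALSE]
    ok <- !missing_aln & !is.na(al$chrom) & al$unique &
      !is.na(al$mapq) & al$mapq >= mapq_min
    ok[is.na(ok)] <- FALSE
    out <- candidates[ok, c("pair_id", "unit", "occ_length"), drop = FALSE]
    out$mate_chrom <- al$chrom[ok]
    out$mate_start <- al$pos[ok]
    out$mate_strand <- al$strand[ok]
    out$mapq <- al$mapq[ok]
    out$source <- "mate"
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- nrow(candidates) - nrow(out)
  out
}

#' Cluster mate anchors along the genome
#'
#' Single-linkage grouping per (unit, chromosome): anchors whose mate
#' positions are within `window` bases of the previous anchor join the same
#' cluster.  The default window of 300 bp is the average paired-end insert
#' size, so both flanks of one locus merge into a single cluster.
#'
#' @param anchors Output of [anchor_mates()].
#' @param window Maximum gap between consecutive anchors in a cluster.
#' @param read_length Read length; the cluster window is
#'   `[min mate_start, max mate_start + read_length)`.
#' @return List of clusters; each is a list with `chrom`, `unit`, `start`,
#'   `end` (0-based half-open window), `n_anchors` and the anchor rows.
#' @export
cluster_anchors <- function(anchors, window = 300L, read_length = 100L) {
  stopifnot(is.data.frame(anchors))
  if (!nrow(anchors)) return(list())
  anchors <- anchors[order(anchors$unit, anchors$mate_chrom,
                           anchors$mate_start), , drop = FALSE]
  key <- paste(anchors$unit, anchors$mate_chrom, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    a <- anchors[key == k, , drop = FALSE]
    gap <- c(0L, diff(a$mate_start))
    grp <- cumsum(gap > window | c(TRUE, rep(FALSE, nrow(a) - 1L)))
    for (g in unique(grp)) {
      ag <- a[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        chrom = ag$mate_chrom[1], unit = ag$unit[1],
        start = min(ag$mate_start),
        end = max(ag$mate_start) + as.integer(read_length),
        n_anchors = nrow(ag), anchors = ag)
    }
  }
  out
}

#' Cluster length-frequency distribution
#'
#' Counts anchored occurrence lengths into bins `l_min .. read_length`
#' (missing lengths count zero).
#'
#' @param cluster A cluster from [cluster_anchors()].
#' @param l_min Smallest binned length (default 50, the anchoring threshold).
#' @param read_length Read length (top bin).
#' @return Named integer vector of bin counts.
#' @export
cluster_freq <- function(cluster, l_min = 50L, read_length = 100L) {
  bins <- l_min:read_length
  len <- pmin(cluster$anchors$occ_length, read_length)
  counts <- tabulate(match(len, bins), nbins = length(bins))
  setNames(as.integer(counts), bins)
}

#' Smirnov-Grubbs outlier score for the full-length bin
#'
#' Tests whether the top (full-read-length) bin of a cluster's frequency
#' distribution is an upper outlier.  The t-score is
#' `(f_top - mu) / sigma` with `mu`, `sigma` the mean and standard deviation
#' of the `N` bin counts; the one-sided p-value is
#' `min(1, N * P(T_{N-2} > tau))` with
#' `tau^2 = N (N-2) t^2 / ((N-1)^2 - N t^2)`, and 0 when
#' `t^2 >= (N-1)^2 / N`.  With the default 51 bins (lengths 50..100),
#' `p < 5e-9` exactly when `t > 5.27`.
#'
#' @param freq Numeric vector of bin counts (>= 3 bins); the last element is
#'   the full-length bin `f_top`.
#' @param sd_type `"population"` (divide by N; default) or `"sample"`
#'   (divide by N-1) standard deviation.
#' @return List with `t_score`, `p_value`, `f_top`, `mean`, `sd`, `n_bins`
#'   and `degenerate` (`TRUE` when `sigma == 0`, in which case the score is
#'   undefined and no call can be made).
#' @export
grubbs_score <- function(freq, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  freq <- as.numeric(freq)
  n <- length(freq)
  if (n < 3L) stop("grubbs_score needs at least 3 bins")
  f_top <- freq[n]
  mu <- mean(freq)
  sigma <- sqrt(sum((freq - mu)^2) /
                  (if (sd_type == "population") n else n - 1L))
  if (sigma == 0) {
    return(list(t_score = NA_real_, p_value = NA_real_, f_top = f_top,
                mean = mu, sd = sigma, n_bins = n, degenerate = TRUE))
  }
  t <- (f_top - mu) / sigma
  list(t_score = t, p_value = grubbs_pvalue(t, n), f_top = f_top, mean = mu,
       sd = sigma, n_bins = n, degenerate = FALSE)
}

#' One-sided Smirnov-Grubbs p-value
#'
#' @param t t-score of the top bin (`(f_top - mean) / sd`).
#' @param n Number of bins.
#' @return p-value in `[0, 1]`; 1 for non-positive scores, 0 when the score
#'   reaches its algebraic maximum.
#' @export
grubbs_pvalue <- function(t, n) {
  stopifnot(n >= 3L)
  vapply(t, function(ti) {
    if (is.na(ti)) return(NA_real_)
    if (ti <= 0) return(1)
    d <- (n - 1)^2 - n * ti^2
    if (d <= 0) return(0)
    tau <- sqrt(n * (n - 2) * ti^2 / d)
    min(1, n * stats::pt(tau, df = n - 2, lower.tail = FALSE))
  }, numeric(1))
}

#' Smallest t-score significant at a given level
#'
#' Scans two-decimal t-scores and returns the smallest with
#' `grubbs_pvalue(t, n) < p_target`.  With `n = 51` and
#' `p_target = 5e-9` this reproduces the calling threshold t > 5.27.
#'
#' @param n Number of bins.
#' @param p_target Significance level.
#' @return The threshold t-score (two decimals).
#' @export
grubbs_threshold <- function(n = 51L, p_target = 5e-9) {
  ts <- seq(0.01, floor(100 * (n - 1) / sqrt(n)) / 100, by = 0.01)
  p <- grubbs_pvalue(ts, n)
  hit <- which(p < p_target)
  if (!length(hit)) stop("no two-decimal t-score reaches p_target")
  ts[hit[1]]
}

#' Call significantly expanded STR loci
#'
#' A cluster is called significant when its Grubbs p-value is below
#' `alpha / n_windows` (Bonferroni over the ~10 million insert-sized genomic
#' windows: 0.05 / 1e7 = 5e-9 by default), it has at least `min_anchors`
#' anchors, and no control sample shows a full-read-length occurrence of the
#' unit at the locus.
#'
#' @param clusters List of case clusters from [cluster_anchors()].
#' @param control_anchors List (one per control) of anchor tables from
#'   [anchor_mates()] run on the control samples, used for the per-locus
#'   control-absence clause; anchors overlapping a cluster window (padded by
#'   `window`) with `occ_length == read_length` veto the call.
#' @param control_histograms Optional list of control `str_histogram`s; when
#'   supplied (and `control_scope = "genome"`), a unit's genome-wide control
#'   full-length count vetoes calls instead (fallback when controls were not
#'   anchored).
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_windows Number of tested genomic windows (default 1e7).
#' @param min_anchors Minimum cluster size (default 5).
#' @param l_min,read_length Binning as in [cluster_freq()].
#' @param window Padding around the cluster window for the control overlap.
#' @param control_scope `"locus"` (default) or `"genome"`.
#' @param sd_type Passed to [grubbs_score()].
#' @param relax Optional relaxed p-value threshold overriding
#'   `alpha / n_windows` to consider more candidates with less evidence.
#' @return An object of class `str_calls`: a `data.frame` with one row per
#'   cluster (`chrom`, `start`, `end`, `unit`, `n_anchors`, `f_top`,
#'   `t_score`, `p_value`, `control_full`, `significant`), sorted by
#'   p-value.
#' @export
call_expansions <- function(clusters, control_anchors = list(),
                            control_histograms = list(), alpha = 0.05,
                            n_windows = 1e7, min_anchors = 5L, l_min = 50L,
                            read_length = 100L, window = 300L,
                            control_scope = c("locus", "genome"),
                            sd_type = "population", relax = NULL) {
  control_scope <- match.arg(control_scope)
  p_thresh <- if (is.null(relax)) alpha / n_windows else relax
  rows <- lapply(clusters, function(cl) {
    fr <- cluster_freq(cl, l_min = l_min, read_length = read_length)
    g <- grubbs_score(fr, sd_type = sd_type)
    ctrl_full <- if (control_scope == "locus") {
      sum(vapply(control_anchors, function(a) {
        if (!nrow(a)) return(0L)
        hit <- a$unit == cl$unit & a$mate_chrom == cl$chrom &
          a$mate_start < cl$end + window &
          a$mate_start + read_length > cl$start - window &
          a$occ_length >= read_length
        sum(hit)
      }, integer(1)))
    } else {
      sum(vapply(control_histograms, function(h) {
        fc <- full_length_counts(h)
        if (cl$unit %in% names(fc)) as.integer(fc[[cl$unit]]) else 0L
      }, integer(1)))
    }
    data.frame(chrom = cl$chrom, start = cl$start, end = cl$end,
               unit = cl$unit, n_anchors = cl$n_anchors, f_top = g$f_top,
               t_score = if (g$degenerate) NA_real_ else g$t_score,
               p_value = if (g$degenerate) NA_real_ else g$p_value,
               control_full = ctrl_full,
               significant = !g$degenerate && !is.na(g$p_value) &&
                 g$p_value < p_thresh && ctrl_full == 0L &&
                 cl$n_anchors >= min_anchors,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), unit = character(0),
                         n_anchors = integer(0), f_top = numeric(0),
                         t_score = numeric(0), p_value = numeric(0),
                         control_full = integer(0), significant = logical(0),
                         stringsAsFactors = FALSE)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "p_threshold") <- p_thresh
  class(out) <- c("str_calls", "data.frame")
  out
}

#' @export
print.str_calls <- function(x, ...) {
  cat("STR expansion calls:", nrow(x), "cluster(s),", sum(x$significant),
      "significant (p <", format(attr(x, "p_threshold")), ")\n")
  if (nrow(x)) {
    show <- as.data.frame(x)
    # 1-based inclusive coordinates for the human-readable report
    show$start <- show$start + 1L
    print(head(show, 10L), row.names = FALSE)
    if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more\n")
  }
  invisible(x)
}
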