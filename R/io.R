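## Standard-format readers and writers (FASTA, FASTQ, SAM, TSV, BED).
## Coordinates are 0-based half-open internally; SAM input (1-based) is
## converted on read, BED output is emitted 0-based half-open.

#' Read / write FASTA
#'
#' @param path FASTA file path (gzip accepted on read).
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read paired FASTQ files into linked read pairs
#'
#' Mates are linked by record order; ids are taken from the first file with
#' any trailing `/1` stripped.  Gzip input is accepted.  Quality strings are
#' ignored (scanning uses sequence only).
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @return `data.frame` with `pair_id`, `seq1`, `seq2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(r1) != length(r2))
    stop("mate count mismatch: ", basename(path1), " has ", length(r1),
         " records, ", basename(path2), " has ", length(r2))
  ids <- sub("\\s.*$", "", names(r1))
  ids <- sub("/[12]$", "", ids)
  data.frame(pair_id = ids, seq1 = as.character(r1),
             seq2 = as.character(r2), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq_pairs
#' @param pairs `data.frame` with `pair_id`, `seq1`, `seq2`.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  q <- function(s) Biostrings::BStringSet(strrep("I", nchar(s)))
  s1 <- Biostrings::DNAStringSet(pairs$seq1)
  names(s1) <- paste0(pairs$pair_id, "/1")
  s2 <- Biostrings::DNAStringSet(pairs$seq2)
  names(s2) <- paste0(pairs$pair_id, "/2")
  Biostrings::writeXStringSet(s1, path1, format = "fastq",
                              qualities = q(pairs$seq1))
  Biostrings::writeXStringSet(s2, path2, format = "fastq",
                              qualities = q(pairs$seq2))
  invisible(c(path1, path2))
}

#' Read mate alignments from a SAM file
#'
#' Parses a text SAM produced by an external aligner (e.g. BWA-MEM) via
#' Rsamtools, extracting per read: chromosome, 0-based position, strand and
#' MAPQ.  A read is flagged non-unique when it is unmapped, has MAPQ 0, or
#' has secondary/supplementary records.  Read ids are reported as
#' `"<qname>/1"` / `"<qname>/2"` using the first/last-segment FLAG bits
#' (plain `<qname>` for unpaired records).
#'
#' @param path SAM file (with header) or BAM file.
#' @return `data.frame` with `read_id`, `chrom`, `pos` (0-based), `strand`,
#'   `mapq`, `unique`.
#' @export
read_mate_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam <- if (is_sam) {
    dest <- tempfile(fileext = ".bam")
    Rsamtools::asBam(path, sub("\\.bam$", "", dest), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq"))
  a <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (!length(a$qname))
    return(data.frame(read_id = character(0), chrom = character(0),
                      pos = integer(0), strand = character(0),
                      mapq = integer(0), unique = logical(0),
                      stringsAsFactors = FALSE))
  flag <- a$flag
  paired <- bitwAnd(flag, 0x1) > 0L
  unmapped <- bitwAnd(flag, 0x4) > 0L
  secondary <- bitwAnd(flag, 0x100) > 0L
  supplementary <- bitwAnd(flag, 0x800) > 0L
  first <- bitwAnd(flag, 0x40) > 0L
  read_id <- ifelse(paired,
                    paste0(a$qname, "/", ifelse(first, "1", "2")),
                    a$qname)
  df <- data.frame(read_id = read_id, chrom = as.character(a$rname),
                   pos = a$pos - 1L, strand = as.character(a$strand),
                   mapq = a$mapq, unmapped = unmapped,
                   ambig = secondary | supplementary,
                   stringsAsFactors = FALSE)
  multi <- unique(df$read_id[df$ambig])
  primary <- df[!df$ambig, , drop = FALSE]
  # one primary record per read id expected
  primary <- primary[!duplicated(primary$read_id), , drop = FALSE]
  primary$unique <- !primary$unmapped &
    !(primary$read_id %in% multi) &
    !is.na(primary$mapq) & primary$mapq > 0L
  primary$chrom[primary$unmapped] <- NA_character_
  primary$pos[primary$unmapped] <- NA_integer_
  rownames(primary) <- NULL
  primary[, c("read_id", "chrom", "pos", "strand", "mapq", "unique")]
}

#' Occurrence / histogram TSV round trips
#'
#' Plain TSV serializations of the per-read occurrence table (the scan
#' output contract: unit, span, length, mutation counts, flanks, mate link)
#' and of per-sample histograms (`sample_id`, `unit`, `length`, `count`,
#' mergeable across shards).
#'
#' @param occ Occurrence `data.frame` from [scan_reads()].
#' @param path Output path.
#' @export
write_occurrences_tsv <- function(occ, path) {
  if ("read_id" %in% names(occ) && !"mate_id" %in% names(occ)) {
    # reads named <pair>/1, <pair>/2 link to their mates
    paired <- grepl("/[12]$", occ$read_id)
    mate <- rep(NA_character_, nrow(occ))
    mate[paired] <- paste0(sub("/[12]$", "", occ$read_id[paired]), "/",
                           ifelse(endsWith(occ$read_id[paired], "/1"),
                                  "2", "1"))
    occ <- cbind(occ[, "read_id", drop = FALSE], mate_id = mate,
                 occ[, setdiff(names(occ), "read_id"), drop = FALSE])
  }
  write.table(occ, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences_tsv
#' @export
read_occurrences_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = NA)
}

#' @rdname write_occurrences_tsv
#' @param h `str_histogram` object.
#' @export
write_histogram_tsv <- function(h, path) {
  stopifnot(inherits(h, "str_histogram"))
  df <- data.frame(sample_id = h$sample_id, read_length = h$read_length,
                   h$counts, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences_tsv
#' @export
read_histogram_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "read_length", "unit", "length", "count")
                %in% names(df)))
  structure(list(sample_id = df$sample_id[1],
                 read_length = as.integer(df$read_length[1]),
                 counts = df[, c("unit", "length", "count")]),
            class = "str_histogram")
}

#' Write expansion calls as BED6+
#'
#' Columns: chrom, 0-based half-open window, unit as name, anchor count as
#' score, `"."` strand, then `f_top`, `t_score`, `p_value`, `control_full`,
#' `significant`.
#'
#' @param calls `str_calls` object from [call_expansions()].
#' @param path Output path.
#' @export
write_calls_bed <- function(calls, path) {
  df <- data.frame(chrom = calls$chrom, start = calls$start,
                   end = calls$end, name = calls$unit,
                   score = calls$n_anchors, strand = ".",
                   f_top = calls$f_top, t_score = calls$t_score,
                   p_value = calls$p_value,
                   control_full = calls$control_full,
                   significant = calls$significant,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
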