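## Synthetic references, implanted expansions and paired-end reads.
##
## The simulator reproduces the statistical structure the pipeline assumes:
## uniform random reference, implanted repeat tracts (optionally compound,
## on one haplotype of a diploid), paired-end fragments with a truncated
## normal insert-size distribution (default 325 bp +/- 10%) and i.i.d.
## substitution errors.  Everything is deterministic per seed.

#' Simulate a uniform random reference sequence
#'
#' @param length Reference length in bases.
#' @param seed Integer seed (reproducible per seed).
#' @return A single DNA string.
#' @export
sim_reference <- function(length, seed = 1L) {
  stopifnot(length > 0)
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Build an STR expansion sequence
#'
#' `str_tract()` is a plain `unit` repeated `copies` times.
#' `sca31_expansion()` emulates the compound intronic insertion associated
#' with spinocerebellar ataxia type 31: ordered segments
#' `(TGGAA)_i (TAGAA)_j (TAGAA|TGGAA|TGGGAA)_k (TGGAA)_l (TAAAATAGAA)_m`,
#' the mixed block cycling its three motifs.  The segment order and mixing
#' rule are a synthetic emulation (only the motifs and copy-number ranges of
#' the real insertion are published), sufficient to exercise compound-repeat
#' handling.
#'
#' @param unit,copies Motif and copy number for a plain tract.
#' @param i,j,k,l,m Segment copy numbers for the compound tract.
#' @return A DNA string.
#' @export
str_tract <- function(unit, copies) {
  stopifnot(copies >= 1)
  strrep(unit, copies)
}

#' @rdname str_tract
#' @export
sca31_expansion <- function(i = 2L, j = 220L, k = 10L, l = 46L, m = 90L) {
  mixed <- paste(rep_len(c("TAGAA", "TGGAA", "TGGGAA"), k), collapse = "")
  paste0(strrep("TGGAA", i), strrep("TAGAA", j), mixed,
         strrep("TGGAA", l), strrep("TAAAATAGAA", m))
}

#' Implant STR expansions into a reference
#'
#' Inserts each tract at its reference position (0-based: the tract goes in
#' between positions `pos - 1` and `pos`).  In diploid mode the expansion is
#' present on one haplotype and absent from the other, the typical state of
#' a heterozygous repeat-expansion carrier.
#'
#' @param ref Reference DNA string.
#' @param implants `data.frame` with columns `pos` (0-based insertion
#'   point), `unit` and `copies`; an optional `seq` column overrides
#'   `unit`/`copies` with an explicit (e.g. compound) insertion sequence.
#' @param diploid If `TRUE` (default) return the expanded haplotype plus an
#'   unmodified copy of the reference.
#' @return List with `haplotypes` (character vector) and `truth`
#'   (`data.frame`: `pos`, `unit`, `inserted_length`).
#' @export
implant_expansion <- function(ref, implants, diploid = TRUE) {
  stopifnot(is.character(ref), length(ref) == 1L)
  n <- nchar(ref)
  if (is.null(implants) || !nrow(implants)) {
    truth <- data.frame(pos = integer(0), unit = character(0),
                        inserted_length = integer(0),
                        stringsAsFactors = FALSE)
    haps <- if (diploid) c(hap1 = ref, hap2 = ref) else c(hap1 = ref)
    return(list(haplotypes = haps, truth = truth))
  }
  stopifnot(all(c("pos", "unit") %in% names(implants)))
  seqs <- if ("seq" %in% names(implants) && any(!is.na(implants$seq))) {
    ifelse(is.na(implants$seq),
           strrep(implants$unit, implants$copies), implants$seq)
  } else {
    strrep(implants$unit, implants$copies)
  }
  ord <- order(implants$pos)
  pos <- as.integer(implants$pos[ord])
  seqs <- seqs[ord]
  if (any(pos < 0L | pos > n))
    stop("implant position outside the reference")
  if (anyDuplicated(pos))
    stop("overlapping implants: positions must be distinct")
  pieces <- character(2L * length(pos) + 1L)
  prev <- 0L
  for (idx in seq_along(pos)) {
    pieces[2L * idx - 1L] <- substr(ref, prev + 1L, pos[idx])
    pieces[2L * idx] <- seqs[idx]
    prev <- pos[idx]
  }
  pieces[2L * length(pos) + 1L] <- substr(ref, prev + 1L, n)
  hap1 <- paste(pieces, collapse = "")
  truth <- data.frame(pos = pos, unit = canonical_unit(implants$unit[ord]),
                      inserted_length = nchar(seqs),
                      stringsAsFactors = FALSE)
  haps <- if (diploid) c(hap1 = hap1, hap2 = ref) else c(hap1 = hap1)
  list(haplotypes = haps, truth = truth)
}

#' Simulate paired-end reads from haplotypes
#'
#' Fragments are placed uniformly along the haplotypes (weighted by
#' haplotype length); insert sizes are normal with mean `insert_mean` and sd
#' `insert_sd`, truncated below at `2 * read_length`; the two reads of a
#' pair face inward from the fragment ends (read 2 is reverse-complemented);
#' substitution errors are i.i.d. per base.
#'
#' @param haplotypes Character vector of haplotype sequences.
#' @param coverage Total fold coverage; the number of pairs is
#'   `round(coverage * L / (2 * read_length))` with `L` the mean haplotype
#'   length.  Ignored when `n_pairs` is given.
#' @param n_pairs Number of pairs to simulate (optional).
#' @param read_length Read length in bases (default 100).
#' @param insert_mean,insert_sd Insert-size distribution; defaults 325 bp
#'   and 10% of the mean.
#' @param error_rate Per-base substitution probability (default 0.001).
#' @param seed Integer seed.
#' @param id_prefix Prefix for pair identifiers.
#' @return `data.frame` with `pair_id`, `seq1`, `seq2` plus provenance
#'   columns `hap`, `frag_start` (0-based on the haplotype) and `insert`.
#' @export
simulate_read_pairs <- function(haplotypes, coverage = 50, n_pairs = NULL,
                                read_length = 100L, insert_mean = 325,
                                insert_sd = insert_mean / 10,
                                error_rate = 0.001, seed = 1L,
                                id_prefix = "pair") {
  stopifnot(length(haplotypes) >= 1L, coverage > 0 || !is.null(n_pairs),
            error_rate >= 0, error_rate <= 1,
            insert_mean >= 2 * read_length)
  hap_len <- nchar(haplotypes)
  if (any(hap_len < insert_mean + 4 * insert_sd))
    stop("haplotype shorter than the maximum insert size")
  set.seed(seed)
  if (is.null(n_pairs))
    n_pairs <- round(coverage * mean(hap_len) / (2 * read_length))
  n_pairs <- as.integer(n_pairs)
  hap <- sample.int(length(haplotypes), n_pairs, replace = TRUE,
                    prob = hap_len)
  ins <- pmax(2L * as.integer(read_length),
              as.integer(round(rnorm(n_pairs, insert_mean, insert_sd))))
  ins <- pmin(ins, hap_len[hap])
  frag_start <- floor(runif(n_pairs) * (hap_len[hap] - ins + 1))
  seq1 <- substr(haplotypes[hap], frag_start + 1L,
                 frag_start + read_length)
  seq2 <- substr(haplotypes[hap], frag_start + ins - read_length + 1L,
                 frag_start + ins)
  seq2 <- dna_revcomp(seq2)
  if (error_rate > 0) {
    seq1 <- add_substitutions(seq1, error_rate)
    seq2 <- add_substitutions(seq2, error_rate)
  }
  data.frame(pair_id = sprintf("%s%06d", id_prefix, seq_len(n_pairs)),
             seq1 = seq1, seq2 = seq2, hap = hap,
             frag_start = as.integer(frag_start), insert = ins,
             stringsAsFactors = FALSE)
}

# i.i.d. substitutions: each erroneous base is replaced by one of the three
# other bases uniformly
add_substitutions <- function(seqs, rate) {
  rl <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), rl, rate)
  hit <- which(n_err > 0L)
  if (!length(hit)) return(seqs)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(rl[i], n_err[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}
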