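toy_pairs <- function() {
  # end1 of p1 carries an 80-bp AC tract; p2 only a 30-bp tract; p3 is
  # repetitive on both ends
  filler <- function(seed, n = 100) { set.seed(seed); random_dna(n) }
  data.frame(
    pair_id = c("p1", "p2", "p3"),
    seq1 = c(paste0(strrep("AC", 40), substr(filler(1), 1, 20)),
             paste0(strrep("AC", 15), substr(filler(2), 1, 70)),
             strrep("AC", 50)),
    seq2 = c(filler(3), filler(4), strrep("AG", 50)),
    stringsAsFactors = FALSE)
}

test_that("anchor pairs require one long STR side and one clean side", {
  cand <- select_anchor_pairs(toy_pairs(), min_len = 50L)
  expect_identical(cand$pair_id, "p1")
  expect_identical(cand$str_end, 1L)
  expect_identical(cand$unit, "AC")
  expect_gte(cand$occ_length, 80L)
  expect_identical(cand$mate_seq, toy_pairs()$seq2[1])
  expect_identical(attr(cand, "n_both_repetitive"), 1L)
})

test_that("builtin anchoring demands a single exact hit over both strands", {
  set.seed(5)
  ref <- random_dna(5000)
  mate_fwd <- substr(ref, 1001, 1100)
  mate_rev <- r_revcomp(substr(ref, 2001, 2100))
  dup_ref <- paste0(ref, substr(ref, 3001, 3100))  # duplicates a segment
  cand <- data.frame(pair_id = c("a", "b", "c"), unit = "AC",
                     str_end = 1L, occ_length = 100L,
                     mate_seq = c(mate_fwd, mate_rev,
                                  substr(ref, 3001, 3100)),
                     stringsAsFactors = FALSE)
  anc <- anchor_mates(cand, mode = "builtin",
                      reference = c(chr1 = dup_ref))
  expect_identical(anc$pair_id, c("a", "b"))
  expect_identical(anc$mate_start, c(1000L, 2000L))
  expect_identical(anc$mate_strand, c("+", "-"))
  expect_identical(attr(anc, "n_dropped"), 1L)
})

test_that("a long unique STR-side flank places the locus directly", {
  set.seed(6)
  ref <- random_dna(5000)
  # STR-side read: 40-bp flank copied from the reference, then repeat
  flank <- substr(ref, 3001, 3040)
  cand <- data.frame(pair_id = "f1", unit = "AC", str_end = 1L,
                     occ_length = 60L,
                     mate_seq = substr(ref, 3301, 3400),
                     flank_left = flank, flank_right = "",
                     stringsAsFactors = FALSE)
  anc <- anchor_mates(cand, mode = "builtin", reference = c(chr1 = ref))
  expect_identical(anc$source, "flank")
  expect_identical(anc$mate_start, 3000L)
  # short flanks fall back to the mate
  cand$flank_left <- substr(flank, 1, 20)
  anc2 <- anchor_mates(cand, mode = "builtin", reference = c(chr1 = ref))
  expect_identical(anc2$source, "mate")
  expect_identical(anc2$mate_start, 3300L)
  # disabling flank placement forces the mate route
  cand$flank_left <- flank
  anc3 <- anchor_mates(cand, mode = "builtin", reference = c(chr1 = ref),
                       flank_min = 1000L)
  expect_identical(anc3$source, "mate")
})

test_that("SAM-mode anchoring honours FLAG and MAPQ semantics", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chr1\tLN:100000",
    # q1 mate 2: clean primary, MAPQ 60 -> unique anchor at 0-based 1500
    "q1\t129\tchr1\t1501\t60\t100M\t*\t0\t0\t*\t*",
    # q2 mate 2: MAPQ 0 -> multi-mapped
    "q2\t129\tchr1\t2501\t0\t100M\t*\t0\t0\t*\t*",
    # q3 mate 2: has a secondary record -> ambiguous
    "q3\t129\tchr1\t3501\t60\t100M\t*\t0\t0\t*\t*",
    "q3\t385\tchr1\t4501\t60\t100M\t*\t0\t0\t*\t*",
    # q4 mate 2: mapped but below the MAPQ cutoff
    "q4\t129\tchr1\t5501\t5\t100M\t*\t0\t0\t*\t*"), sam)
  al <- read_mate_alignments(sam)
  expect_identical(al$pos[al$read_id == "q1/2"], 1500L)
  expect_false(al$unique[al$read_id == "q2/2"])
  expect_false(al$unique[al$read_id == "q3/2"])
  cand <- data.frame(pair_id = c("q1", "q2", "q3", "q4"), unit = "AC",
                     str_end = 1L, occ_length = 100L, mate_seq = "",
                     stringsAsFactors = FALSE)
  anc <- anchor_mates(cand, mode = "sam", alignments = al, mapq_min = 20L)
  expect_identical(anc$pair_id, "q1")
  expect_identical(anc$mate_start, 1500L)
  expect_identical(attr(anc, "n_dropped"), 3L)
})

test_that("anchors cluster by single linkage within the insert window", {
  a <- data.frame(pair_id = paste0("p", 1:3), unit = "AC",
                  occ_length = c(100L, 80L, 100L), mate_chrom = "chr1",
                  mate_start = c(1000L, 1050L, 1100L), mate_strand = "+",
                  mapq = NA_integer_, stringsAsFactors = FALSE)
  cl <- cluster_anchors(a, window = 300L, read_length = 100L)
  expect_identical(length(cl), 1L)
  expect_identical(cl[[1]]$start, 1000L)
  expect_identical(cl[[1]]$end, 1200L)
  expect_identical(cl[[1]]$n_anchors, 3L)
  b <- a[1:2, ]
  b$mate_start <- c(1000L, 2000L)
  expect_identical(length(cluster_anchors(b, window = 300L)), 2L)
  # different units never share a cluster
  c_ <- a
  c_$unit <- c("AC", "AG", "AC")
  expect_identical(length(cluster_anchors(c_, window = 300L)), 2L)
})

test_that("the Grubbs score matches direct arithmetic and its inversion", {
  freq <- c(rep(0, 50), 10)  # f50..f99 = 0, f100 = 10
  g <- grubbs_score(freq)
  mu <- 10 / 51
  sigma <- sqrt(((10 - mu)^2 + 50 * mu^2) / 51)
  expect_equal(g$t_score, (10 - mu) / sigma, tolerance = 1e-12)
  # this configuration attains the algebraic maximum sqrt(N-1): p = 0
  expect_equal(g$t_score, sqrt(50), tolerance = 1e-12)
  expect_identical(g$p_value, 0)
  # a non-extreme configuration, checked against an independent evaluation
  freq2 <- c(rep(1, 45), 0, 2, 1, 3, 2, 9)
  g2 <- grubbs_score(freq2)
  n <- 51
  t2 <- g2$t_score
  tau <- sqrt(n * (n - 2) * t2^2 / ((n - 1)^2 - n * t2^2))
  expect_equal(g2$p_value, min(1, n * pt(tau, n - 2, lower.tail = FALSE)),
               tolerance = 1e-12)
})

test_that("degenerate distributions are flagged and never called", {
  g <- grubbs_score(rep(3, 51))
  expect_true(g$degenerate)
  expect_true(is.na(g$t_score))
  cl <- list(list(chrom = "c", unit = "AC", start = 0L, end = 100L,
                  n_anchors = 51L,
                  anchors = data.frame(occ_length = rep(75L, 51))))
  calls <- call_expansions(cl, min_anchors = 1L)
  expect_false(calls$significant)
})

test_that("the Grubbs p-value is a strictly decreasing probability", {
  ts <- seq(0.5, 7, by = 0.25)
  p <- grubbs_pvalue(ts, 51)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) <= 0))                  # non-increasing throughout
  interior <- p > 0 & p < 1                       # strict between the caps
  expect_true(all(diff(p[interior]) < 0))
  expect_identical(grubbs_pvalue(-1, 51), 1)
  expect_identical(grubbs_pvalue(7.1, 51), 0)  # beyond the algebraic max
})

test_that("significance needs Bonferroni p, control absence and support", {
  expect_identical(0.05 / 1e7, 5e-9)
  mk_cluster <- function(n_full = 30L) {
    list(chrom = "chr1", unit = "AAAATAGAAT", start = 1000L, end = 1700L,
         n_anchors = n_full + 5L,
         anchors = data.frame(occ_length = c(rep(100L, n_full),
                                             60L, 65L, 70L, 75L, 80L)))
  }
  calls <- call_expansions(list(mk_cluster()))
  expect_true(calls$significant)
  expect_lt(calls$p_value, 5e-9)
  # one overlapping control full-length anchor vetoes the call
  ctrl <- data.frame(pair_id = "c1", unit = "AAAATAGAAT",
                     occ_length = 100L, mate_chrom = "chr1",
                     mate_start = 1200L, mate_strand = "+",
                     mapq = NA_integer_, stringsAsFactors = FALSE)
  vet <- call_expansions(list(mk_cluster()), control_anchors = list(ctrl))
  expect_false(vet$significant)
  expect_identical(vet$control_full, 1L)
  # a control anchor elsewhere (or short) does not veto
  far <- ctrl; far$mate_start <- 50000L
  short <- ctrl; short$occ_length <- 60L
  expect_true(call_expansions(list(mk_cluster()),
                              control_anchors = list(far))$significant)
  expect_true(call_expansions(list(mk_cluster()),
                              control_anchors = list(short))$significant)
  # genome-scope fallback uses control histograms
  ctrl_hist <- str_histogram(
    data.frame(read_id = "r1", unit = "AAAATAGAAT", length = 100L),
    read_length = 100L, sample_id = "ctrl")
  gen <- call_expansions(list(mk_cluster()),
                         control_histograms = list(ctrl_hist),
                         control_scope = "genome")
  expect_false(gen$significant)
  # minimum anchor support
  few <- call_expansions(list(mk_cluster()), min_anchors = 100L)
  expect_false(few$significant)
  # relaxation flag loosens the p threshold
  weak <- list(chrom = "chr1", unit = "AAAATAGAAT", start = 1000L,
               end = 1700L, n_anchors = 13L,
               anchors = data.frame(
                 occ_length = c(rep(100L, 3),
                                rep(c(60L, 65L, 70L, 75L, 80L), each = 2))))
  strictly <- call_expansions(list(weak))
  relaxed <- call_expansions(list(weak), relax = 1e-2)
  expect_gte(strictly$p_value, 5e-9)
  expect_false(strictly$significant)
  expect_true(relaxed$significant)
})
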