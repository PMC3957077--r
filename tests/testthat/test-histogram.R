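make_hist <- function(counts, read_length = 100L, sample_id = "s") {
  # counts: data.frame(unit, length, count) -> str_histogram via a fake
  # occurrence table (one read per count)
  rows <- counts[rep(seq_len(nrow(counts)), counts$count), , drop = FALSE]
  occ <- data.frame(read_id = paste0("r", seq_len(nrow(rows))),
                    unit = rows$unit, length = rows$length,
                    stringsAsFactors = FALSE)
  str_histogram(occ, read_length = read_length, sample_id = sample_id)
}

test_that("accumulation counts one read per unit at its longest occurrence", {
  occ <- scan_reads(rep(strrep("AC", 50), 10),
                    read_ids = paste0("r", 1:10), flanks = FALSE)
  h <- str_histogram(occ, read_length = 100, sample_id = "toy")
  expect_identical(h$counts,
                   data.frame(unit = "AC", length = 100L, count = 10L,
                              stringsAsFactors = FALSE))
  # a read with two same-unit tracts contributes only its longest
  rd <- paste0(strrep("AC", 15), "GGGGGGGGGG", strrep("AC", 5))
  occ2 <- scan_read(rd, flanks = FALSE)
  h2 <- str_histogram(occ2, read_length = nchar(rd))
  ac <- h2$counts[h2$counts$unit == "AC", ]
  expect_identical(ac$length, 30L)
  expect_identical(ac$count, 1L)
})

test_that("histograms refuse occurrences longer than the read", {
  occ <- data.frame(read_id = "r1", unit = "AC", length = 120L)
  expect_error(str_histogram(occ, read_length = 100), "inconsistent")
})

test_that("merging histograms is additive, associative and commutative", {
  h1 <- make_hist(data.frame(unit = "AC", length = 100L, count = 3L))
  h2 <- make_hist(data.frame(unit = "AC", length = 100L, count = 4L))
  h3 <- make_hist(data.frame(unit = c("AC", "AG"), length = c(80L, 100L),
                             count = c(2L, 5L)))
  m <- merge_histograms(h1, h2)
  expect_identical(m$counts$count[m$counts$unit == "AC" &
                                    m$counts$length == 100L], 7L)
  a <- merge_histograms(merge_histograms(h1, h2), h3)
  b <- merge_histograms(h1, merge_histograms(h2, h3))
  c_ <- merge_histograms(h3, h2, h1)
  expect_identical(a$counts, b$counts)
  expect_identical(a$counts, c_$counts)
  expect_error(merge_histograms(h1, make_hist(
    data.frame(unit = "AC", length = 50L, count = 1L), read_length = 50L)),
    "read lengths")
})

test_that("an implanted tract produces a full-read-length peak", {
  set.seed(61)
  ref <- sim_reference(20000, seed = 71)
  imp <- implant_expansion(ref, data.frame(pos = 10000, unit = "AGAGGC",
                                           copies = 50), diploid = FALSE)
  pairs <- simulate_read_pairs(imp$haplotypes, coverage = 50,
                               error_rate = 0, seed = 72)
  occ <- scan_reads(c(pairs$seq1, pairs$seq2),
                    read_ids = c(paste0(pairs$pair_id, "/1"),
                                 paste0(pairs$pair_id, "/2")),
                    flanks = FALSE)
  h <- str_histogram(occ, read_length = 100, sample_id = "sim")
  u <- canonical_unit("AGAGGC")
  cu <- h$counts[h$counts$unit == u, ]
  expect_gt(cu$count[cu$length == 100L], 0)
  expect_gt(length(unique(cu$length)), 3)  # partial-overlap spread
})

test_that("sensing requires case abundance and strict control absence", {
  case <- make_hist(data.frame(unit = c("AAAATAGAAT", "AC"),
                               length = c(100L, 100L), count = c(25L, 40L)))
  clean <- make_hist(data.frame(unit = "AC", length = 100L, count = 30L))
  dirty <- make_hist(data.frame(unit = c("AAAATAGAAT", "AC"),
                                length = c(100L, 100L), count = c(1L, 30L)))
  got <- sense_expanded_units(case, list(clean, clean))
  expect_identical(got$unit, "AAAATAGAAT")
  expect_identical(got$case_full, 25L)
  # one control full-length read vetoes the unit
  expect_identical(nrow(sense_expanded_units(case, list(clean, dirty))), 0L)
  # strict inequality at the threshold
  boundary <- make_hist(data.frame(unit = "AAAATAGAAT", length = 100L,
                                   count = 10L))
  expect_identical(nrow(sense_expanded_units(boundary, list(clean),
                                             min_full_reads = 10L)), 0L)
  eleven <- make_hist(data.frame(unit = "AAAATAGAAT", length = 100L,
                                 count = 11L))
  expect_identical(nrow(sense_expanded_units(eleven, list(clean),
                                             min_full_reads = 10L)), 1L)
})

test_that("sensing without controls warns and is monotone in controls", {
  case <- make_hist(data.frame(unit = "AGC", length = 100L, count = 20L))
  expect_warning(got <- sense_expanded_units(case, list()), "case-only")
  expect_identical(got$unit, "AGC")
  # adding counts to a control can only shrink the reported set
  ctrl0 <- make_hist(data.frame(unit = "AT", length = 50L, count = 1L))
  ctrl1 <- make_hist(data.frame(unit = "AGC", length = 100L, count = 1L))
  s0 <- sense_expanded_units(case, list(ctrl0))
  s1 <- sense_expanded_units(case, list(merge_histograms(ctrl0, ctrl1)))
  expect_true(all(s1$unit %in% s0$unit))
})

test_that("the relaxed control condition uses a length cutoff", {
  case <- make_hist(data.frame(unit = "AGC", length = 100L, count = 20L))
  ctrl <- make_hist(data.frame(unit = "AGC", length = 95L, count = 2L))
  expect_identical(nrow(sense_expanded_units(case, list(ctrl))), 1L)
  expect_identical(nrow(sense_expanded_units(case, list(ctrl),
                                             control_max_length = 90L)), 0L)
})

test_that("compare_distributions returns long-format tables", {
  h1 <- make_hist(data.frame(unit = "AC", length = c(60L, 100L),
                             count = c(2L, 5L)), sample_id = "a")
  h2 <- make_hist(data.frame(unit = "AC", length = 90L, count = 3L),
                  sample_id = "b")
  tab <- compare_distributions("AC", list(h1, h2))
  expect_identical(nrow(tab), 3L)
  expect_identical(attr(tab, "max_length")[["a"]], 100L)
  expect_identical(attr(tab, "max_length")[["b"]], 90L)
  expect_identical(nrow(compare_distributions("CG", list(h1, h2))), 0L)
  one <- compare_distributions("AC", list(h1))
  expect_identical(nrow(one), 2L)
})

test_that("biological replicates give concordant maxima for abundant units", {
  ref <- sim_reference(20000, seed = 81)
  imp <- implant_expansion(ref, data.frame(pos = 8000, unit = "AGAGGC",
                                           copies = 60), diploid = FALSE)
  hist_of <- function(seed) {
    pairs <- simulate_read_pairs(imp$haplotypes, coverage = 50,
                                 error_rate = 0, seed = seed)
    occ <- scan_reads(c(pairs$seq1, pairs$seq2), flanks = FALSE)
    str_histogram(occ, read_length = 100, sample_id = paste0("rep", seed))
  }
  r1 <- hist_of(91)
  r2 <- hist_of(92)
  u <- canonical_unit("AGAGGC")
  tab <- compare_distributions(u, list(r1, r2))
  mx <- attr(tab, "max_length")
  expect_identical(length(mx), 2L)
  expect_lte(abs(mx[[1]] - mx[[2]]), 10L)
})
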