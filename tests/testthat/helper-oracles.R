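# Independent pure-R oracles used across tests.  These deliberately avoid the
# package's C++ routines so that agreement is a genuine cross-check.

r_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

r_rotations <- function(s) {
  n <- nchar(s)
  vapply(0:(n - 1), function(r) {
    paste0(substr(s, r + 1, n), substr(s, 1, r))
  }, character(1))
}

r_primitive_root <- function(s) {
  n <- nchar(s)
  for (d in seq_len(n %/% 2)) {
    if (n %% d == 0 &&
        s == strrep(substr(s, 1, d), n / d)) return(substr(s, 1, d))
  }
  s
}

r_canonical <- function(s) {
  root <- r_primitive_root(s)
  min(c(r_rotations(root), r_rotations(r_revcomp(root))))
}

all_kmers <- function(k, alphabet = c("A", "C", "G", "T")) {
  do.call(paste0, expand.grid(rep(list(alphabet), k),
                              stringsAsFactors = FALSE))
}

# Orbit partition of primitive k-mers under rotation + reverse complement,
# built purely from string operations.
r_orbits <- function(k) {
  km <- all_kmers(k)
  prim <- km[vapply(km, function(s) nchar(r_primitive_root(s)) == k,
                    logical(1))]
  orbit_of <- vapply(prim, r_canonical, character(1))
  split(prim, orbit_of)
}

# Direct-from-definition maximal-repetition enumeration in plain R (cubic);
# for tiny ACGT strings only.
r_maximal_repetitions <- function(s) {
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  rows <- list()
  if (n >= 2) {
    for (l in 1:(n - 1)) {
      for (r in (l + 1):n) {
        len <- r - l + 1
        p <- 0
        for (q in 1:(len - 1)) {
          if (all(ch[l:(r - q)] == ch[(l + q):r])) { p <- q; break }
        }
        if (p == 0 || len < 2 * p) next
        if (l > 1 && ch[l - 1] == ch[l - 1 + p]) next
        if (r < n && ch[r + 1] == ch[r + 1 - p]) next
        rows[[length(rows) + 1]] <-
          data.frame(start = as.integer(l - 1), end = as.integer(r),
                     unit = paste(ch[l:(l + p - 1)], collapse = ""),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      unit = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
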