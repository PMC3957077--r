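## Non-redundant (representative) repeat units.
##
## An STR occurrence can be described by many unit strings: any rotation of
## the unit, any whole-number power of it, and -- because reads come from
## either strand -- any rotation of its reverse complement.  To avoid double
## counting, every unit is reduced to a single representative: the primitive
## root, minimized lexicographically (A < C < G < T) over all rotations of
## itself and of its reverse complement.

#' Primitive root of a DNA string
#'
#' Returns the shortest prefix `p` such that `s` is a whole-number
#' concatenation of `p`; a primitive string maps to itself.  For example the
#' repeat unit of `ACACACAC` is `AC`, not `ACAC`.
#'
#' @param s Character vector of non-empty ACGT strings (case-insensitive).
#' @return Character vector of primitive roots, one per input.
#' @examples
#' minimal_unit(c("ACACACAC", "CAG", "AAAA"))
#' @export
minimal_unit <- function(s) {
  if (length(s) == 0L) return(character(0))
  cpp_minimal_unit(as.character(s))
}

#' Canonical (representative) repeat unit
#'
#' Reduces a unit to its primitive root, then takes the lexicographic minimum
#' (alphabet order A < C < G < T) over all rotations of the root and all
#' rotations of its reverse complement.  Canonicalization is idempotent and
#' invariant under rotation and reverse complement, so occurrences of e.g.
#' `GGGTTA` and `AACCCT` repeats are counted as the same unit.
#'
#' @param u Character vector of non-empty ACGT strings.
#' @return Character vector of canonical units.
#' @examples
#' canonical_unit("GGGTTA")  # "AACCCT"
#' canonical_unit("CA")      # "AC"
#' @export
canonical_unit <- function(u) {
  if (length(u) == 0L) return(character(0))
  cpp_canonical_unit(as.character(u))
}

#' Enumerate representative repeat units of length k
#'
#' Returns exactly one representative per equivalence class of primitive
#' k-mers under rotation and reverse complement, together with the class
#' (orbit) size.  Classes are disjoint and jointly cover all primitive
#' k-mers.
#'
#' @param k Unit length (single positive integer).
#' @param max_k Configured upper bound on the unit length; enumeration cost
#'   grows as `k * 4^k`, so the default cap is 12 (enough to cover 10-mer
#'   disease units such as the SCA31 repeat).
#' @return A `data.frame` with columns `k`, `unit` and `class_size`, sorted
#'   by `unit`.
#' @examples
#' representative_units(2)  # AC, AG, AT, CG
#' @export
representative_units <- function(k, max_k = 12L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("k must be a single integer >= 1")
  if (k > max_k)
    stop("k exceeds the configured maximum unit length (", max_k, ")")
  out <- cpp_representative_units(k)
  data.frame(k = k, unit = out$unit, class_size = out$class_size,
             stringsAsFactors = FALSE)
}

#' Reverse complement of DNA strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
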