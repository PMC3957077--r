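Package: strsense
Title: Ab Initio Detection of Long Short Tandem Repeat Expansions from
    Paired-End Short Reads
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects short tandem repeat (STR) expansions that are longer
    than the sequencing read length, without a reference catalogue of repeat
    loci. Reads are scanned for maximal exact repetitions which are greedily
    extended into approximate STR occurrences tolerating single-base edits;
    per-unit length histograms are compared between a case sample and
    controls to sense expanded repeat units; reads filled by an STR are then
    localized through the unique alignment of their paired-end mates, anchor
    clusters are formed, and significantly expanded loci are called with a
    one-sided Smirnov-Grubbs outlier test under Bonferroni correction.
    Includes a paired-end read simulator with implanted expansions for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    BiocGenerics,
    Biostrings,
    IRanges,
    Rsamtools,
    data.table,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
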