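---
title: "Detecting STR expansions longer than the read length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting STR expansions longer than the read length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strsense)
```

## The problem

Short tandem repeats (STRs) — repeats with 2–6 nt units — cause a family of
genetic diseases when they expand, and the pathogenic alleles often span
hundreds to thousands of bases.  Short-read sequencing produces ~100 bp
reads: a read drawn from inside such an expansion is filled wall-to-wall
with the repeat, maps nowhere (or everywhere) on the reference, and carries
no positional information of its own.  Catalogue-based genotypers handle
repeats short enough to leave mappable flanks inside a read; expansions
*longer than the read* need a different signal.

`strsense` uses two such signals:

1. **Abundance.** An expansion of length `L` in a genome sequenced at
   coverage `c` contributes about `c · (L − r) / r` reads that consist of
   the repeat end-to-end (read length `r`).  Full-read-length occurrences
   of a unit that are frequent in the case sample but absent from every
   control sample indicate a case-specific expansion.
2. **Paired-end anchoring.** Although the repeat-filled read is
   unmappable, its mate — one insert length away — usually maps uniquely.
   Clustering the mates of repeat-filled reads localizes the expansion to
   within about one insert size.

## Canonical repeat units

One repeat tract can be written many ways: rotations of the unit, powers of
it, and (since reads come from either strand) rotations of its reverse
complement.  Every unit is therefore reduced to a *representative* form:
the primitive root (shortest string whose repetition reconstructs the
unit), minimized lexicographically (A < C < G < T) over all rotations of
the root and of its reverse complement.  The paper's convention does not
state the alphabet order; A < C < G < T is the standard DNA convention and
is consistent with the representative forms the package reproduces
(e.g. the telomeric repeat family is reported as `AACCCT`):

```{r}
canonical_unit(c("GGGTTA", "ACACACAC", "CA"))
representative_units(2)
```

Canonicalization is exact: tests verify invariance under rotation and
reverse complement exhaustively for all units up to length 6, and the class
sizes against independent brute-force orbit counting.  Non-ACGT characters
never participate: the canonical algebra is defined over ACGT only, so
scanning treats any other base as a hard block boundary.

## Scanning reads

A *repetition* is a string `x^k x'` with `k ≥ 2` and `x'` a proper prefix
of `x`; it is *maximal* if it cannot be extended with the same unit.  Three
observations shape the scanner:

- Enumerating all **maximal exact repetitions** of a read is sufficient to
  find every repeat seed, and can be done in `O(n log n)`.  The
  implementation enumerates, for each period `p`, anchor positions spaced
  `p` apart: any repetition of exponent ≥ 2 spans two consecutive anchors,
  and longest-common-extension scans recover its maximal span.  Spans are
  reported once, under their minimal period, whose unit is automatically
  primitive (a span maximal under period `p` is maximal under its minimal
  period `q`, and `q` divides `p` — so deduplicating by span and keeping
  the smallest period yields exactly the set of maximal repetitions after
  unit minimization).  A direct-from-definition cubic enumerator is kept
  alongside as a testing oracle, and a third, pure-R enumerator checks the
  oracle itself on small inputs.
- Real STRs are **approximate**.  Exhaustive approximate-repetition search
  is exponential in the allowed mutations, so each exact seed is extended
  greedily: at each boundary a single mismatch, insertion or deletion
  against the periodic continuation of the unit is accepted only when it is
  followed (outward) by at least `|unit|` exact periodic bases.  Three
  conventions are left open by that rule and fixed here: the left boundary
  is extended to exhaustion before the right (the two sides are
  independent except at read edges); when several single edits qualify the
  preference is mismatch > deletion > insertion (consuming read bases
  first); and the phase of the periodic continuation is fixed by the seed's
  frame, with indel edits shifting it.  Under these conventions the
  package reproduces the printed worked example — extending an exact
  `(CAG)₆CA` seed across two mismatches and one deletion:

```{r}
rd <- paste0("CGCCCGCAGCGCAT", strrep("CAG", 6), "CA", "TCAGGGA")
extend_approximate(rd, 14, 34, "CAG")
```

  One consequence of frame bookkeeping is worth noting: a single-base
  interruption between two in-phase tracts (e.g. `(AC)₁₀ T (AC)₃`) is
  classified as an *insertion*, because a mismatch would shift the frame of
  the following tract.  The mutation count — the quantity reported
  downstream — is one either way.
- A read may contain **overlapping occurrences of the same unit**; only
  the longest is kept (ties go to the leftmost, a determinism choice).
  Occurrences of different units may legitimately overlap (nested
  periodicities), and all are reported.

Homopolymer runs are detected but excluded from default reporting
(`unit_range = c(2, 6)`), matching the STR definition; passing
`unit_range = c(1, …)` re-enables them, and raising the upper bound (to 10
or 12) catches longer disease units — the SCA31 unit below is a 10-mer.
The default minimum occurrence length is `2·|unit|` (the seed's own
minimum); downstream stages apply their own thresholds.

Quality scores are ignored throughout: the method uses sequence only.

## Sensing expansions from histograms

Per sample, each read contributes at most one count per unit — its longest
occurrence of that unit — to a `(unit, length)` histogram.  Counting reads
rather than occurrences makes the full-read-length bin directly
interpretable as "reads filled by the repeat".  Histograms merge
additively, so shards can be accumulated and a control database grown
incrementally.

`sense_expanded_units()` reports units with **strictly more than**
`min_full_reads = 10` full-read-length occurrences in the case and **zero**
in every control.  The strict inequality follows the ">10 occurrences"
convention of the source method; the absence condition is exact zero by
default, with an optional relaxed cutoff ("no occurrence ≥ L") because
near-full-length occurrences typically accompany full-length ones in
resequencing replicates.  "Full read length" generalizes the original
"100-bp occurrence" so any uniform read length works.

## Locating and calling

1. **Candidate pairs**: one end carries an occurrence ≥ 50 bp of a sensed
   unit, the other end is clean; pairs repetitive on both ends are
   unanchorable and dropped (counted in the run report).
2. **Anchoring**: when the STR-side read retains a flank of ≥ 30 bases
   that matches the reference uniquely, the locus is placed directly from
   the flank (the classical within-read placement); otherwise the clean
   mate is placed, either from an external aligner's SAM (BWA-MEM is
   consumed, never re-implemented; unique = mapped, no
   secondary/supplementary record, MAPQ ≥ 20 by default) or by the
   built-in exact-match search against a supplied reference (unique =
   exactly one hit over both strands).  The built-in mode is intended for
   simulated and small references where exact search is adequate; in SAM
   mode only mate anchoring is available, since flank placement would
   require invoking the aligner.
3. **Clustering**: single linkage per (unit, chromosome) with a 300 bp
   window — the average insert size — so anchors from both sides of one
   locus merge into one cluster.
4. **Calling**: in each cluster, occurrence lengths are binned from 50 bp
   to the read length (51 bins for 100-bp reads; missing lengths count 0).
   If the expansion is longer than the read, the top bin `f_top` is an
   outlier.  The Smirnov–Grubbs t-score is `(f_top − μ)/σ` over the bins,
   and the one-sided p-value is `min(1, N · P(T_{N−2} > τ))` with
   `τ² = N(N−2)t² / ((N−1)² − Nt²)` (0 when `t² ≥ (N−1)²/N`).

Two conventions were verified numerically rather than assumed.  With
`N = 51`, the smallest two-decimal t-score with `p < 5×10⁻⁹` is **5.27**
under the one-sided inversion — matching the method's printed threshold —
whereas a two-sided (factor `2N`) version gives 5.31; one-sided is
therefore the default.  σ uses the population (divide-by-N) form, with
`sd_type = "sample"` switchable; the two differ only by a factor
`√(N/(N−1))` on the t-scale.

```{r}
grubbs_threshold(n = 51, p_target = 5e-9)
```

A call is significant when `p < alpha / n_windows` — Bonferroni over the
~10⁷ insert-sized windows of a human genome, giving 0.05/10⁷ = 5×10⁻⁹ —
**and** no control shows a full-length occurrence of the unit at the locus
**and** the cluster has at least `min_anchors = 5` anchors.  The anchor
floor avoids degenerate single-read clusters (the source method is silent
here; 5 reads is well below the ~25 expected at 50× coverage for a true
expansion, and large enough that a lone chimeric pair cannot call a
locus).  Degenerate clusters (σ = 0) are flagged and never called.  The
control-absence clause is evaluated per locus (control anchors overlapping
the padded cluster window); a genome-wide per-unit fallback via control
histograms is provided for controls that were never anchored.  A `relax`
argument loosens the p threshold to surface candidates with less evidence.

Coordinates are 0-based half-open internally and in BED output; printed
reports use 1-based positions, the convention of genome browsers.

## The simulator, and what passing tests show

`sim_reference()` draws a uniform random ACGT sequence;
`implant_expansion()` inserts repeat tracts (compound templates supported,
e.g. `sca31_expansion()`, which emulates the published SCA31 segment
motifs — the exact segment layout of the real insertion is not fully
published, so the template is synthetic) on one haplotype of a diploid;
`simulate_read_pairs()` draws fragments uniformly, with truncated-normal
insert sizes (default 325 bp ± 10%, the typical paired-end library) and
i.i.d. substitution errors (default 0.001).  Defaults mirror the study
conditions used throughout the tests: 100-kb reference, a 500-bp
`(AAAATAGAAT)₅₀` implant, 50× 2×100 bp coverage, three control samples.
At these sizes the full validation (acceptance tests plus a 20-seed
control-only false-positive screen) completes in minutes on one CPU.

The simulator deliberately omits several features of real data: GC-biased
coverage (high-GC expansions are under-covered on real instruments and may
be missed), indel sequencing errors (substitution-only by default — the
scanner's single-edit tolerance is exercised separately), PCR slippage,
and the repeat-dense background of real genomes (centromeres, telomeres,
retrotransposons), which in practice necessitates the control-absence
clause far more than a random background does.  Passing the simulation
tests therefore demonstrates the pipeline's statistical and algorithmic
correctness under its stated model, not robustness to every artefact of
production data.

## Numerical and degenerate-input choices

- Ties in overlap pruning: leftmost occurrence wins (determinism).
- `grubbs_pvalue()` is capped to `[0, 1]`: 1 for `t ≤ 0`, 0 beyond the
  algebraic maximum `t² = (N−1)²/N`; strictly decreasing in between.
- Empty inputs flow through: an empty FASTQ yields empty tables, a
  zero-call report and exit success.
- Sensing with no controls is allowed with a warning (case-only), since a
  control database may not exist yet.
- Insert sizes are truncated at `2·read_length` so mates never overlap
  into nonsense fragments; haplotypes shorter than the maximum insert are
  rejected.

## Known limitations

- The built-in anchorer requires exact mate matches: a sequencing error in
  the mate drops the pair (~10% at the default error rate).  Use SAM mode
  with a real aligner for sensitive anchoring.
- Expansion length beyond "longer than the read" is not estimated; that
  requires long-read follow-up of the called locus.
- Within-read-length repeats (the catalogue-genotyper regime) are out of
  scope; the flank-based placement shortcut applies only when a flank maps
  uniquely.
- The period-anchor scanner is worst-case quadratic on pathological
  (e.g. single-letter) sequences; on reads it behaves linearithmically,
  which is what the throughput tests check.
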