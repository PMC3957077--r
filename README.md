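# strsense

Ab initio detection of short tandem repeat (STR) expansions that are
**longer than the sequencing read length**, from paired-end short reads and
without a reference catalogue of repeat loci.

Disease-associated STR expansions (Huntington's CAG, the C9orf72 GGGGCC
repeat, SCA10's ATTCT, the 10-mer AAAATAGAAT insertion of SCA31, ...) can
span hundreds to thousands of bases.  At ~100 bp read length, reads drawn
from inside such an expansion consist of the repeat wall-to-wall: they map
nowhere or everywhere, so alignment-first pipelines are blind to exactly
the alleles that matter.  `strsense` works read-first instead:

1. **Scan** — every read is scanned for maximal exact repetitions
   (enumerated with a period-anchor algorithm, linearithmic on reads),
   which are greedily extended into *approximate* STR occurrences: at each
   boundary a single mismatch, insertion or deletion is accepted only if
   followed by ≥ |unit| exact periodic bases.  Units are reduced to a
   canonical representative — the primitive root, minimized over rotations
   and reverse-complement rotations (A < C < G < T) — so `GGGTTA` and
   `AACCCT` repeats are one unit.
2. **Sense** — per sample and unit, a histogram of occurrence lengths is
   built (one count per read: its longest occurrence of the unit).  A unit
   with more than 10 *full-read-length* occurrences in the case and zero in
   every control marks a case-specific expansion longer than the read.
3. **Locate & call** — reads filled by a sensed unit are placed through a
   uniquely mapping flank when one remains, otherwise through the unique
   alignment of their paired-end mate; anchors are clustered within the
   insert size (300 bp).  In each cluster the occurrence-length frequency
   distribution over bins 50..read-length is tested for an outlying top bin
   with a one-sided Smirnov–Grubbs test: `t = (f_top − μ)/σ`, and
   `p = min(1, N·P(T_{N−2} > τ))` with `τ² = N(N−2)t²/((N−1)² − Nt²)`.
   A locus is called significant when `p < 0.05/10⁷ = 5×10⁻⁹` (Bonferroni
   over the ~10 million insert-sized windows of a human genome) — with 51
   bins this is `t > 5.27` — provided no control shows a full-length
   occurrence at the locus and the cluster has ≥ 5 anchors.

A seed-deterministic simulator (random reference, implanted expansions —
including compound SCA31-like templates — on one haplotype of a diploid,
truncated-normal insert sizes 325 bp ± 10%, i.i.d. substitution errors)
makes the whole pipeline testable end to end without external data.

## Worked example

Implant a 300-bp `(AAAATAGAAT)₃₀` expansion on one haplotype of a 30-kb
diploid genome, sequence case and one control at 60×, and run the pipeline:

```r
library(strsense)
ref  <- sim_reference(30000, seed = 70)
imp  <- implant_expansion(ref, data.frame(pos = 15000, unit = "AAAATAGAAT",
                                          copies = 30))
case <- simulate_read_pairs(imp$haplotypes, coverage = 60, seed = 71)
ctrl <- simulate_read_pairs(c(ref, ref), coverage = 60, seed = 72)
res  <- run_pipeline(case, list(ctrl), reference = c(ref = ref),
                     unit_range = c(2L, 10L))
print(res)
```

```
strsense run report (read length 100, units 2-10)
case pairs: 9045 (occurrences: 82983)
control pairs: 9000
sensed units (> 10 full-length reads, controls clean): 1
candidate pairs: 80 (both-end repetitive dropped: 7)
unique anchors: 60 (dropped: 20)
clusters: 1; significant calls (p < 5e-09, >= 5 anchors): 1
sensed units:
       unit case_full
 AAAATAGAAT        70
significant expansions (1-based coordinates):
 chrom start   end       unit n_anchors f_top  t_score p_value
   ref 14722 15276 AAAATAGAAT        60    45 7.037913       0
```

Reading the output: 70 case reads are pure `AAAATAGAAT` repeat end-to-end
while the control has none, so the unit is sensed; 80 read pairs carry a
≥ 50 bp occurrence on exactly one end, of which 60 anchor uniquely (7
pairs were repeat on both ends and unanchorable, 20 mates/flanks had no
unique exact hit); they form a single cluster whose window covers the true
insertion point (15,000), with 45 of 60 anchored occurrences in the
full-length bin — an extreme Grubbs outlier (t = 7.04, beyond the
algebraic maximum of the null, hence p = 0 < 5×10⁻⁹).

The raised `unit_range` upper bound matters: the implanted unit is a
10-mer, and as an approximate 5-mer (`AAAAT`) it would need two edits per
unit span, which the single-edit extension rightly refuses.

A thin CLI wrapping the same functions is installed at `exec/strsense`
(subcommands `units`, `scan`, `hist`, `sense`, `simulate`, `locate`).

## Scope

`strsense` reports *that* a locus carries an expansion longer than the
read length and *where* it is (to within about one insert size).  It does
not estimate the expansion's full length (that requires long-read
follow-up of the called locus), genotype within-read-length repeats, or
perform read alignment (external SAM from e.g. BWA-MEM is consumed for
mate anchoring on real references).
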