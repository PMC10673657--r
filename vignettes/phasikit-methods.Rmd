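---
title: "PHAS locus discovery with phasikit: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PHAS locus discovery with phasikit: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological model

Phased secondary siRNAs (phasiRNAs) are produced when a miRNA-guided
cleavage of a precursor transcript sets a fixed starting point from which
DCL proteins dice the double-stranded RNA into head-to-tail 21- or 24-nt
increments. Two signatures follow and both are exploited here:

1. **Register enrichment.** Read 5′ ends pile up at positions congruent
   modulo the cycle length (21 or 24 nt) with the cleavage site. Because
   the dsRNA intermediate carries 2-nt 3′ overhangs, a read from the
   antisense strand whose leftmost genomic coordinate is `p − 2` belongs
   to the same duplex as a sense read starting at `p`; antisense reads
   therefore join the register after a +2-nt shift of their leftmost
   coordinate (`effective_position()`).
2. **Cleavage evidence.** Degradome (PARE) reads report uncapped 5′ ends;
   a degradome read whose 5′ end falls opposite positions 9–11 of an
   sRNA binding site ("valid read") evidences sRNA-guided slicing at that
   site.

## The window statistic

A scan of cycle `c` uses windows of `W = 10c` nt (210 nt for 21-nt
phasiRNAs, 240 nt for 24-nt). A window holds `N = 2W` position/strand
slots of which `K = 20` lie in the anchor register once antisense reads
are shifted. With `n` occupied slots of which `k` in register, the
occupancy surprise is the hypergeometric upper tail
`P(X >= k), X ~ Hyper(N, K, n)` (`hypergeometric_pvalue()`), computed
exactly in log space.

Candidate windows are anchored at occupied effective positions rather
than at every genomic coordinate: a register with no read at its first
position cannot beat a window one cycle downstream, so anchoring loses
no locus while shrinking the candidate set by orders of magnitude.
Anchoring, however, conditions the draw — the anchor slot is occupied
and in-register by construction — and the unconditional tail would be
anti-conservative under the null. Scanned windows are therefore tested with the
anchor-conditional tail `P(X >= k − 1), X ~ Hyper(N−1, K−1, n−1)`
(`anchored_window_pvalue()`); with this form the scan is calibrated on
uniform placements (the suite checks the exceedance at both 0.01 and
0.05). `hypergeometric_pvalue()` retains the unconditional form for
direct use.

Evidence strength is summarised per position by the phase score
`(k − 2) · ln(1 + 10P/(1+U))`, where `P` and `U` are the in- and
out-of-register abundance sums in a window of one scan width centred on
the scored position and `k` the distinct occupied in-register slots;
positions supported by fewer than `min_k = 3` occupied cycles score 0.
The score grows with both the number of supporting cycles and the
signal-to-background abundance ratio, and is indifferent to sequencing
depth scale only through the +1/+10 constants of its ratio.

## From windows to loci

Windows with `P < 0.05` are extended by 100 bp on each side (clamped to
the contig), overlapping extended windows of the same contig and cycle
class are merged transitively, and each merged interval keeps the
minimum member P-value, the anchor of that best member (ties to the
smaller coordinate — this anchor defines the locus register), and the
maximum member phase score. Benjamini–Hochberg correction is applied
separately within each cycle class, since the 21- and 24-nt scans are
separate families of tests. A merged interval is reported as a PHAS
locus when its phase score exceeds 5 *strictly* and its adjusted P-value
is below 0.05; names are `PHAS_<contig>_<serial>` with serials
consecutive per contig in coordinate order, so naming is a pure function
of the calls.

Each occupied in-register (position, strand) slot inside a called locus
yields one phasiRNA, numbered `siR1…` densely in 5′→3′ order; a
register-indexed D-notation (`D8(+)` style) is emitted alongside, with
`D1` at the first occupied in-register position — the cycle the trigger
cleavage sets off. The phasiRNA × library count matrix these produce is
the input differential-expression or ordination analyses would consume;
those analyses are outside this package's scope.

A permutation false-positive rate accompanies each called locus when
requested: read positions inside the locus are redrawn uniformly
(multiplicities and strands preserved) and the locus' best window
P-value is compared with the observed one over `n_permutations`
replicates (default 1000, minimum 100). It is reported as a column and
deliberately not used as a filter.

## Degradome validation

Binding sites are exhaustive ungapped antiparallel alignments — plant
sRNA targeting is near-perfectly complementary, so no seed heuristic or
gap model is needed at these scales. sRNA position `i` pairs transcript
position `t_end − i + 1`; the inferred cleavage position is `t_end − 9`
(opposite sRNA position 10) and the valid-read window is the 3-nt span
`{t_end − 10, t_end − 9, t_end − 8}`. G:U wobbles count as full
mismatches by default; a `gu_half` flag down-weights them to 0.5 for
exploration. Two retention policies are kept deliberately distinct
because they answer different questions:

* **trigger rule** (miRNA triggers of PHAS loci): at least one valid
  read in any profile OR fewer than 4 mismatches;
* **target rule** (phasiRNA targets): at least one valid read AND at
  most 4 mismatches, OR a perfect (0-mismatch) site.

For trigger search the locus precursors are scanned in both
orientations (a PHAS locus is an unstranded genomic interval); antisense
sites can only be retained through the mismatch clause because degradome
profiles are sense-only. Each candidate trigger reports the distance
from its inferred cleavage position to the nearest occupied in-register
position and the register offset modulo the cycle; a trigger that sets
the phase has offset 0 and, when the first cycle is expressed,
distance 0.

TAS3-like loci are annotated independently of the PHAS scan: tasiARF
payloads aligned to both genome strands with at most 2 substitutions,
±250-nt flanks extracted, and miR390-family sites predicted on the
flank; one site on each side of the tasiARF (sides defined on the
strand of the match) is the canonical two-hit architecture and is
labelled `TAS3-like`. Targets are classified `cis` when the targeted
transcript overlaps the phasiRNA's generating locus, `same_family` when
an annotation table links both to one family, else `other`; `cis` takes
precedence.

## The synthetic-data generator

`simulate_dataset()` builds the study conditions every test runs
against: a random genome (default 100 kb over 2 contigs, GC 0.42), five
21-nt and two 24-nt implanted PHAS loci of ten cycles, nine libraries
grouped as three tissues, and one TAS3-like locus. Choices a user may
want to revisit, with the reasoning behind the defaults:

* **Phased abundances** are log-normal (`meanlog = ln(20)`,
  `sdlog = 0.5`) per position per library — sRNA abundances are
  heavy-tailed, and a mean of 20 per position per library corresponds to
  a well-expressed locus without being trivial.
* **Background** reads are uniform over genome and strand at 50
  reads/kb with Poisson(2) counts (zero draws dropped — a zero-count
  read does not exist in a collapsed library), a deliberately
  exchangeable null matching the assumptions of the window test; 10% of
  background reads are copied from the repeat set to exercise the
  repeat filter.
* **Triggers** are 22-nt synthetic miRNAs whose perfect complementary
  site is written into the genome so that the inferred cleavage position
  coincides exactly with phased position 1, and both degradome profiles
  carry `degradome_signal` (default 10) reads at that position.
* **TAS3-like implants** place two miR390-style sites around two
  in-register tasiARF payload copies, with the 3′-site cleavage in
  register with the phased reads. Payloads come from a clearly labelled
  synthetic stand-in FASTA shipped with the package; real analyses
  should supply the conserved Arabidopsis/rice tasiARFs.

The generator is deterministic: one seed drives every draw and identical
configurations reproduce byte-identical files. What it does **not**
emulate — sequencing error, adapter read-through, ligation bias,
expression heterogeneity between tissues, genome repeats beyond the
explicit repeat reads — bounds what green tests mean: they demonstrate
the statistical machinery recovers what its model assumes, not that the
pipeline is robust to every artefact of real libraries.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere internally; BED export is
  0-based half-open, GFF3 stays 1-based.
* The internal mapper is exact-match, full-length, both strands, all
  placements (multi-mapping reads count at every placement; no
  fractional weighting). SAM/BAM import accepts external alignments but
  keeps only ungapped, full-length, mismatch-free records.
* Repeat filtering removes reads occurring exactly (either strand) as a
  substring of a repeat; an empty repeat set is an identity transform
  with a warning.
* Merging uses ≥1 shared nucleotide; `merge(merge(x)) = merge(x)`.
* Ties for the locus register (equal minimum P) resolve to the smaller
  anchor coordinate.
* Empty inputs propagate as valid empty tables, never errors, except
  where the input is malformed (truncated SAM records, missing
  annotation columns) — those fail loudly with context.

## Problem sizes

The suite and the acceptance script run everything on the simulator
defaults above (100-kb genomes, ~5 000 background reads, 20 background
seeds for the specificity check, 1 000–2 000 uniform placements for
calibration, 100–1 000 FPR permutations). These sizes put every
statistic deep in its asymptotic regime for the effects simulated while
keeping a full run in minutes on one core; all thresholds (score 5,
FDR 0.05, extension 100 bp, ≤2 tasiARF mismatches) are the standard
PHAS-calling criteria, not tuning knobs.

## Known limitations

* The 22-nt phasiRNA class and size-profile classification
  (hc-siRNA/NAT-siRNA) are out of scope.
* Sequence-similarity annotation against external databases is replaced
  by a user-supplied annotation-table join; database-dependent counts
  are not reproducible and are not attempted.
* The FPR permutation scheme redraws positions within the merged
  interval only; it measures register concentration, not genome-wide
  window multiplicity (which the BH correction addresses).
* Degradome support for antisense precursor sites is structurally
  unavailable from sense-only profiles; such triggers rely on the
  mismatch clause.
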