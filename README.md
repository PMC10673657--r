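# phasikit

Discovery and annotation of **phased secondary siRNA (phasiRNA) loci** from
small-RNA sequencing data, for plant small-RNA researchers who want a
transparent, fully testable alternative to one-off PHAS-calling scripts.

Phased siRNAs arise when a miRNA-guided cleavage sets a fixed register from
which a precursor is diced into head-to-tail 21- or 24-nt increments.
phasikit implements the complete analysis around that model:

* **Read processing** — collapsing to unique reads with per-library counts,
  21/24-nt selection, exact-match repeat filtering, exact full-length genome
  mapping (or SAM/BAM import).
* **Phase statistics** — the 2-nt antisense offset
  (a minus-strand read at `p − 2` phases with a plus-strand read at `p`),
  window occupancy over `N = 2W` position/strand slots with `K = 20`
  in-register, the exact hypergeometric window test
  `P(X ≥ k), X ~ Hyper(N, K, n)` (anchor-conditional form for scanned
  windows), and the per-position phase score
  `(k − 2)·ln(1 + 10P/(1+U))` with a k ≥ 3 support guard.
* **Locus construction** — 100-bp extension of windows with `P < 0.05`,
  transitive overlap merging keeping the minimum P, Benjamini–Hochberg
  correction per cycle class, calling at phase score > 5 and adjusted
  P < 0.05, `PHAS_<contig>_<serial>` naming, phasiRNA extraction with
  `siR`/D-notation names and a phasiRNA × library count matrix.
* **Degradome (PARE) validation** — exhaustive ungapped antiparallel
  binding-site search, valid reads (5′ ends opposite sRNA positions 9–11),
  the trigger rule (≥1 valid read OR <4 mismatches) and target rule
  ((≥1 valid read AND ≤4 mismatches) OR 0 mismatches), T-plot data.
* **TAS3 annotation and networks** — tasiARF scan (≤2 mismatches, ±250-nt
  flanks), dual miR390-site classification, cis/trans target classes,
  shared-phasiRNA report, and a `PHAS → phasiRNA ⊣ target` edge table.
* **A synthetic-data generator** (`simulate_dataset()`) that implants
  phased loci with duplex-partner reads, triggers with degradome cleavage
  signatures, TAS3-like architectures and background noise — so every
  stage is testable end to end with known truth.

## Worked example

```r
library(phasikit)

bundle <- simulate_dataset(sim_config(seed = 42))
#> phasikit sim bundle: 2 contig(s) (100000 nt), 4483 unique reads, 8 implanted loci

result <- run_pipeline(bundle, pipeline_config(n_permutations = 0))
#> [phasikit] filter     4483 unique reads in
#> [phasikit] filter     3173 reads of length 21/24
#> [phasikit] filter     2897 reads after repeat filtering
#> [phasikit] map        2897 exact placements
#> [phasikit] scan(21)   1404 candidate windows
#> [phasikit] scan(21)   21 merged intervals
#> [phasikit] scan(24)   1393 candidate windows
#> [phasikit] scan(24)   15 merged intervals
#> [phasikit] call       8 PHAS loci
#> [phasikit] extract    161 phasiRNAs
#> [phasikit] triggers   8 candidate triggers
#> [phasikit] targets    81 degradome-supported targets
#> [phasikit] tas3       2 tasiARF matches, 2 TAS3-like

result$loci[, c("name", "contig", "start", "end", "cycle",
                "p_adjusted", "max_phase_score")]
#>           name contig start   end cycle p_adjusted max_phase_score
#> 1 PHAS_ctg01_1  ctg01 14410 14987    21   3.06e-30             166
#> 2 PHAS_ctg01_2  ctg01 39718 40295    21   3.06e-30             157
#> ...
#> 8 PHAS_ctg02_5  ctg02 46751 47328    21   1.16e-30             179

head(result$triggers[, c("srna", "locus", "mismatches", "valid_reads",
                         "dist_to_register")], 3)
#>          srna        locus mismatches valid_reads dist_to_register
#> 1 mir_trig_01 PHAS_ctg01_1          0          20                0
#> 2 mir_trig_05 PHAS_ctg01_2          0          20                0
#> 3 mir_trig_03 PHAS_ctg01_3          0          20                0
```

All eight implanted loci (five 21-nt, two 24-nt, one TAS3-like) are called
with adjusted P-values around 1e-30 and phase scores far above the
call threshold of 5; every implanted trigger miRNA is recovered with a
perfect complementary site whose inferred cleavage position is exactly in
the locus register (`dist_to_register = 0` — the cleavage sets phased
position 1), with `valid_reads` matching the simulated degradome signal.
The two tasiARF payload copies classify as `TAS3-like` because a miR390
site flanks them on each side. `run_pipeline(..., out_dir = )` writes
loci as GFF3/BED, phasiRNAs as FASTA, the count matrix, trigger/target/
network TSVs and a run manifest; `inst/scripts/phasikit` wraps
`simulate` and `run-all` for shell use.

See the methods vignette (`vignettes/phasikit-methods.Rmd`) for the model,
parameter rationale, and what the simulation does and does not emulate.

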