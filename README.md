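# isomirage

IsomiR calling, seed-match target prediction and age-related
anti-correlation screening for small-RNA data — built around the seed
dichotomy of human miR-101 and its abundant 5'-shifted variant.

## What this is for

Small-RNA sequencing shows that an annotated mature miRNA is really a
population of sequence variants (*isomiRs*): 5'/3' trimming variants,
non-templated 3' additions, and internal substitutions. Variants that
shift the 5' end change the seed (positions 2–8) and therefore the
predicted target repertoire. miR-101 is the canonical example: the
miRBase mature `UACAGUACUGUGAUAACUGAA` (seed `ACAGUAC`) co-occurs at
comparable abundance with the one-base-upstream variant
`GUACAGUACUGUGAUAACUGA` (seed `UACAGUA`).

`isomirage` implements the full computational chain for studying such a
dichotomy, for people analysing small-RNA plus expression time-series
data:

* **isomiR calling** — decompose each read against hairpin references
  into `(t5, t3, additions, substitutions)` within the conventional
  bounds (end shifts ≤ 3 nt, ≤ 3 added bases, ≤ 1 substitution), with a
  documented, deterministic precedence rule;
* **seed quantification** — per-seed counts, counts per million
  miRNA-mapped reads, locus percentages, seed ratios, variant-class
  proportions;
* **target prediction** — canonical 8mer / 7mer-m8 / 7mer-A1 seed-match
  sites in 3'UTRs, with 8mer precedence;
* **age-trend detection** — per-gene best-of-eight nonlinear trend
  regression against a constant model (F-test, raw p < 0.01);
* **anti-correlation screen** — for genes that are age-related *and*
  seed-predicted targets of a variant, regress expression on the
  variant's log counts and keep pairs with p < 0.01 and Pearson
  r < −0.70 (strict), then compare per-seed pass sets with the
  continuity-corrected two-proportion chi-square test;
* **synthetic data with planted truth** — a tested generator for reads,
  references, age series and anti-correlated pairs, which is how the
  whole pipeline is validated.

The model notation in brief: a read maps at offset `t5` (5' start minus
mature start; negative = upstream, seed-shifting) and `t3` (templated 3'
end minus mature end); normalized seed abundance is
`count(seed) / count(all miRNA-mapped) × 10⁶`; a planted pair satisfies
`expr = a + b·log(counts + 1) + ε` with `sd(ε) = |b|·sd(x)·√(1/r² − 1)`
so its population correlation is `r`.

## Worked example

```r
library(isomirage)

refs <- make_reference(5, rng_seed = 42)      # miR-101-like hairpin first
call <- map_read_to_hairpin("GUACAGUACUGUGAUAACUGA", refs[[1]])
call$t5
#> [1] -1
call$seed7
#> [1] "UACAGUA"
extract_seed(MIR101_MATURE)
#> [1] "ACAGUAC"
```

The abundant 5' variant maps exactly one nucleotide upstream of the
annotated mature and carries the shifted seed — the two seed groups the
rest of the analysis quantifies and screens separately.

```r
sim  <- simulate_reads(refs, isomir_profile_spec(depth = 2000, rng_seed = 7))
res  <- call_sample(sim$reads, refs)
prof <- build_seed_profile(res$calls, "s1")
sum(normalized_seed_frequency(prof, names(prof$seed_counts)))
#> [1] 1e+06
```

Per-million seed frequencies over a full profile sum to one million by
construction; on error-free simulated reads the caller recovers every
planted label (the test suite asserts this at depth 10,000).

## The analysis workflow

Numbered drivers under `analysis/` run the pipeline end to end on
synthetic data and write tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R          # inputs + planted truth
Rscript analysis/02_call_isomirs.R           # isomiR table, recovery report
Rscript analysis/03_quantify_seeds.R         # seed/locus tables, ratios
Rscript analysis/04_scan_targets.R           # site + target-set tables
Rscript analysis/05_fit_age_models.R         # age-related gene flags
Rscript analysis/06_screen_anticorrelation.R # the final screen
```

A typical run reports 100% label recovery, a predicted-target overlap
around 70% between the two seeds (a structural consequence of the
one-base seed shift — every isomiR 8mer site contains a reference
7mer-A1 site), and full recovery of the planted anti-correlated pairs.

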