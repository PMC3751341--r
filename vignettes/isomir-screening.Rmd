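---
title: "IsomiR calling and the age-related anti-correlation screen: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IsomiR calling and the age-related anti-correlation screen: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomirage)
```

## The problem

Mature microRNAs are not single sequences. Small-RNA sequencing shows, for
almost every annotated miRNA, a cloud of closely related variants —
*isomiRs* — produced by imprecise Drosha/Dicer cleavage (5'/3' trimming
variants), by non-templated nucleotide additions at the 3' end, and by
internal substitutions. Variants that shift the 5' end change the *seed*
(positions 2–8 of the mature sequence), and with it the predicted target
repertoire. Human miR-101 is the motivating case: alongside the annotated
mature `UACAGUACUGUGAUAACUGAA` (seed `ACAGUAC`), brain and blood samples
carry a comparably abundant variant shifted one base upstream,
`GUACAGUACUGUGAUAACUGA` (seed `UACAGUA`). This package implements, as
reusable and tested functions, the computational chain needed to study
such a seed dichotomy end to end:

1. read preprocessing (adapter trimming, collapsing) — `trim_adapter()`,
   `collapse_reads()`;
2. isomiR calling against hairpin references — `map_read_to_hairpin()`,
   `call_sample()`, `classify_variant()`;
3. seed-level quantification and normalization — `build_seed_profile()`
   and friends;
4. canonical seed-match target prediction in 3'UTRs — `scan_utr()`,
   `predicted_targets()`;
5. age-trend detection in expression series — `fit_age_models()`;
6. the anti-correlation screen over predicted targets —
   `screen_anticorrelation()`;
7. a synthetic-data generator with planted ground truth that exercises
   all of the above — `make_reference()`, `simulate_reads()`,
   `simulate_age_dataset()`.

The `analysis/` scripts in the repository run these stages as a numbered
workflow on synthetic data and write their tables under `results/`.

## IsomiR decomposition

A read is explained against an annotated mature locus by a tuple
*(t5, t3, additions, substitutions)*: `t5` is the read's 5' start minus
the mature start on the hairpin (negative = upstream, which shifts the
seed register), `t3` is the *templated* 3' end minus the mature end
(negative = trimmed), `additions` is the non-templated 3' suffix, and
substitutions are internal mismatches against the hairpin. Bounds follow
the conventional isomiR taxonomy: |t5| ≤ 3, |t3| ≤ 3, at most 3 added
bases, at most 1 substitution, applied jointly.

Several tuples can explain one read, so a precedence rule is needed; the
de-facto tools do not document one, and this was a genuinely open design
point. We minimize `(number of substitutions, number of additions,
|t5| + |t3|)` lexicographically, then break remaining ties on `(t5, t3)`
and finally on the mature name. The rationale is to prefer *templated*
explanations: a base that matches the hairpin where it lies needs no
biochemical event at all, an end shift needs only cleavage-site
variability, while substitutions and non-templated additions each invoke
an enzymatic modification. Two consequences worth knowing:

* an added base that matches the hairpin flank is absorbed into `t3`
  (additions are exactly the maximal non-templated suffix);
* a mismatch at the terminal position is reported as an addition (with
  `t3 = -1`), not as a substitution — consistent with additions being
  defined by non-templated identity.

Multi-mapping reads are resolved to a single best locus with the same
objective and a deterministic name tie-break; we do not distribute
fractional counts. This keeps every downstream count integral and every
run reproducible, at the cost of a known divergence risk from tools that
split counts across loci.

Coordinates are 0-based half-open internally; the sign convention above
is chosen so that "upstream/downstream of the reference" maps directly
onto the sign of the offset.

## Seed quantification

Counts are aggregated by the *observed* 7-mer at read positions 2–8, so
a substitution inside the seed founds a new seed group — the seed
dichotomy under study is defined on observed sequences, not on intended
loci. Normalization is counts per million miRNA-mapped reads: the
denominator is the total count assigned to any miRNA locus in the
sample, so normalized frequencies over a full profile sum to 10^6 by
construction (a conservation identity the tests assert exactly).
Variant-class proportions are reported over disjoint composite labels
(`trim5+trim3`, ...) so they sum to 1; a marginal any-`trim5` /
any-`add3` view is available separately. Reporting tables apply the
conventional "more than 10 counts" filter — strictly greater, so a
count of exactly 10 is dropped.

## Seed-match target sites

For a seed s (miRNA positions 2–8), the canonical site types on the mRNA
are: **8mer** = reverse complement of positions 2–8 followed by A;
**7mer-m8** = reverse complement of positions 2–8; **7mer-A1** = reverse
complement of positions 2–7 followed by A. At a shared locus the
stronger type wins (8mer > 7mer-m8 > 7mer-A1), so each site interval is
reported once. Only exact seed pairing on the sense strand is scored: no
conservation filtering, context scores or 3'-supplementary pairing,
which keeps the predictor a pure, reproducible function of sequence.

Because the two miR-101 seeds are the same sequence shifted by one base,
their site vocabularies interlock: every 8mer site of the shifted seed
(`UACUGUAA`) begins with the reference seed's 7mer-A1 site (`UACUGUA`).
Any UTR carrying an isomiR 8mer site is therefore automatically a
predicted target of the reference seed too. This containment is the
mechanistic reason the two predicted target sets overlap by roughly
70% even on random sequence, and it is checked exhaustively in the test
suite.

## Age-trend detection

A gene is *age-related* when some member of a family of eight trend
models fits its expression-versus-age profile significantly better than
a constant. The family actually used in the literature this analysis
descends from is not published in enumerable form, so the default here
is a documented reconstruction: polynomials of degree 1–4 in age and
degree 1–4 in `log2(age + 0.25 yr)`. The log branch gives infancy
(days–years) leverage comparable to late decades; the 0.25-year offset
keeps an age of 2 days finite and was fixed once, before any testing, as
roughly a quarter of the first year. The predictor is min–max scaled to
[0, 1] before orthogonal polynomial expansion purely for numerical
conditioning — F-test p-values are invariant to that affine map. The
family is a plain list, so other bases can be substituted.

Each model is tested against the intercept-only model with the overall
regression F-test; the best model is the one with the smallest p (ties
toward fewer parameters), and the gene is flagged when that p is
strictly below 0.01 with **no multiple-testing correction** — that is
the procedure as specified, reproduced faithfully.

One statistical property of this rule deserves emphasis: *flagging on
the minimum p over eight correlated tests is a union, and its null rate
is not 1%*. Under the default family and a 12-point design, simulation
puts the null flag rate near 4–5%. The per-model tests are exactly
calibrated (the unit suite verifies the linear member against the
closed-form regression test), but the best-of-family selection inflates
the family-wise rate, and no choice of correlated model family can both
select the best of eight and hold the union at the nominal level. The
package reports what the rule actually does rather than pretending to a
calibration it cannot have; an acceptance check that expects the union
rate to sit in a 1% binomial band fails by design and is documented as
such.

## The anti-correlation screen

A gene is tested against a miRNA variant only when it is age-related
*and* carries a seed match for that variant. For each gated pair,
expression is regressed on `log(counts + 1)` of the variant
(ordinary least squares; the pseudocount of 1 makes zero counts finite
and is configurable). A pair passes when the regression p-value is
strictly below 0.01 and the Pearson correlation is strictly below
−0.70 — both thresholds strict, mirroring "lower than". For a single
predictor the model F-test and the slope t-test coincide, an identity
the tests check numerically. The overlap between the per-seed passing
sets is compared with the continuity-corrected two-proportion chi-square
test (`prop.test` semantics), applied to (common genes, per-seed
totals) — the reading of the published overlap statistic we judged most
consistent with its methods; this is an interpretation, and it is
isolated in one function.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions:

* **Reference**: random hairpins with 20-nt flanks around an embedded
  mature; the first hairpin is miR-101-like (the annotated mature,
  preceded by G so the upstream variant is templated). Matures are kept
  at pairwise Hamming distance ≥ 8 and every non-true hairpin window at
  distance ≥ 4 from every mature. Under these guards a read carrying at
  most one substitution cannot be decomposed at a wrong locus, which is
  what licenses the 100%-label-recovery check; relaxing them voids that
  guarantee.
* **Reads**: 5' offsets concentrated at 0 (60%) and −1 (30%) to mirror a
  miR-101-like seed dichotomy; 3' ends more ragged (50% at 0); 15% of
  reads carry 1–3 non-templated additions with the A/U-rich base bias
  (0.4/0.4/0.1/0.1) typical of post-transcriptional tailing; 5% carry
  one internal substitution placed ≥ 3 bases from either end so it
  cannot masquerade as an end variant; optional uniform per-base
  sequencing error, off by default. Planted addition bases are redrawn
  until they differ from the hairpin base they would occupy, keeping
  them genuinely non-templated.
* **Age series**: 12 time points from 2 days (0.005 yr) to 98 years.
  Age-related genes follow randomly drawn family members with unit
  signal amplitude plus Gaussian noise (default sd 0.5, i.e.
  signal-to-noise 2); null genes are pure noise. Planted
  anti-correlated pairs set expression to `a + b·log(counts + 1) + ε`
  with `b = −1` and `sd(ε) = |b|·sd(x)·√(1/r² − 1)`, which makes the
  population correlation equal the requested target; Monte-Carlo checks
  confirm the mean sample correlation sits within 0.03 of the target at
  n = 12.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: realistic expression-level distributions,
locus-dependent variant spectra, ligation and PCR biases of small-RNA
library preparation, quality-score structure, genomic multi-mapping
outside the provided hairpins, and any correlation structure among genes
beyond the planted pairs. Recovery rates on this simulator are upper
bounds on real-data performance, not estimates of it.

All simulators take an integer seed, are bit-reproducible across
platforms (R's default integer-state generator, no hash-order
dependence), and restore the caller's RNG state on exit.

## Numerical choices and degenerate inputs

* Sequences are normalized to the RNA alphabet (`T` → `U`) on ingest and
  emitted as stored.
* Adapter trimming defaults: TruSeq small-RNA 3' adapter, minimum
  overlap 6, mismatch fraction ≤ 0.1; a leftmost full-adapter occurrence
  beats any suffix match. Collapsing keeps 16–28-nt reads; both
  windowless quantities (the number of dropped reads) and the window are
  reported/configurable.
* A constant expression row gets p = 1 (no trend), not an error; a
  constant age vector is a rank-deficient design and *is* an error.
  Constant vectors in the pair regression are errors (correlation
  undefined).
* Degenerate seeds whose 7mer-m8 and 7mer-A1 site strings coincide
  (`UUUUUUU`) are reported once with the stronger type.
* Ties everywhere break deterministically (documented objective, then
  lexicographic names), so identical inputs give byte-identical tables.

## Problem sizes

The bundled workflow and checks run at sizes chosen to make their
statistical assertions sharp but quick on one core: 20,000 reads over 5
hairpins for the calling stage, 10,000 reads for exact label recovery,
50,000 for the planted 2:1 seed-ratio recovery, 2,000 null genes for the
age-model null rate, 10,000 replicates for regression-null uniformity,
and 10 planted + 200 null pairs for screen power. Each is stated where
it is used and can be scaled up without code changes.

## Known limitations

* The eight-model family is a reconstruction; results that depend on the
  exact basis (notably which genes sit just under p = 0.01) will differ
  from analyses using the original unpublished family.
* Counts are not distributed across multi-mapping loci.
* Target prediction is seed-match only; no conservation or context
  scoring, so predicted target sets are supersets of what a
  conservation-filtered tool would report.
* The screen is marginal per pair: no covariates, no partial
  correlations, no joint multi-miRNA model.
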