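---
title: "Copy-specific ERV amplicon quantification: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-specific ERV amplicon quantification: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroamp)
```

## The problem

Human endogenous retrovirus families such as HERV-K (HML-2) are present as
on the order of a hundred proviral copies that are nearly identical in
sequence. Bulk measurements (a qPCR assay against a conserved segment, or a
family-level RNA-seq count) cannot say *which* copy is transcribed. A
degenerate primer pair against a conserved proviral segment (here, an
ENV-like region) amplifies many copies at once; deep sequencing of the
amplicon pool and careful read-to-copy attribution then yields a per-copy
expression profile. `retroamp` implements that workflow end to end on
synthetic data with known ground truth:

1. **in-silico PCR** — enumerate the genomic loci the primer pair can
   amplify;
2. **read preparation** — primer trimming and a strict length filter;
3. **alignment** — end-to-end (no soft clipping) glocal alignment with a
   seeded random choice among equal best hits;
4. **quantification** — per-locus counts and per-sample relative
   frequencies (%);
5. **group statistics** — median-based fold change, a symmetric
   relative-fold-change transform, and a simplified negative-binomial Wald
   test with Benjamini–Hochberg FDR control;
6. **qPCR arithmetic** — the 2^-ddCt estimator with replicate gating and a
   no-RT contamination check.

## In-silico PCR

A primer site is a genome window whose bases are each contained in the
corresponding primer base's IUPAC set. Two tunables control the scan:
`max_mismatches` per primer (default 2) and `three_prime_protected`
(default 3): a mismatch within the protected 3'-terminal bases blocks
extension, so such windows are rejected outright. A locus is any correctly
oriented (forward site ... reverse-complemented reverse site) pair whose
span lies in the amplicon window (default 100–2000 bp), on either strand.
Overlapping and nested amplicons are all reported — there is no greedy
suppression rule, and downstream counting treats loci independently.
Coordinates are 0-based half-open internally and BED on output; locus
labels are `<chrom>-<k>` in per-chromosome coordinate order.

Candidate windows come from `Biostrings::matchPattern` with pattern
ambiguities treated as wildcards; the protection rule, orientation
handling, pairing and labelling are applied on top. The test suite checks
the whole scan against a naive all-positions oracle and against planted
fixtures, including a reverse-complement symmetry property.

## Read preparation

Each read end is checked against both primers (the protocol is unstranded:
a read may start from either primer), with an IUPAC-aware Hamming budget
(`trim_budget`, default 1 mismatch — a deliberately small allowance, since
a primer footprint that survives untrimmed still maps inside its locus). The length filter keeps reads whose **post-trim** length
is strictly greater than 135 bp: the floor protects the mapped portion of
the read; the rule is deliberately strict ("reads > 135 bp", so a
135 bp read is dropped and a 136 bp read kept).

## Alignment

Scoring is match +1, mismatch −10, gap −10 **per gap base** — a linear
per-base penalty with no separate gap-open term, the minimal reading of a
single gap figure. An affine scheme would be a configuration extension. "No soft clipping" is realized
as read-global alignment: dynamic programming in which every read base is
scored, starting at any reference position (free reference prefix/suffix).
All positions achieving the maximum score are returned, on both strands.

A read is called *mapped* when its best score reaches `read_len - 33`,
i.e. at most three penalized events (each substitution or gap base
forfeits one match and incurs −10). The threshold is configurable; instrument mapping pipelines leave this
boundary implicit, so the package makes the event budget explicit and
configurable.

Two code paths exist. `align_read_glocal()` is the exhaustive DP, used on
small references and as the reference implementation in tests.
`map_reads()` scales to a genome by pigeonhole seeding: the read is split
into `n_chunks` (default 4) disjoint chunks; any placement with at most
`n_chunks - 1` penalized events leaves one chunk intact, whose leading
31-mer matches the reference exactly, so candidate diagonals anchored at
exact k-mer hits are complete for every placement within the acceptance
budget. Placements beyond the budget would be called unmapped anyway.
Candidate diagonal clusters are re-aligned with the exhaustive DP on a
±`band` (default 8 bp) window.

Equal best hits are resolved "random among best hits". The draw is a
53-bit hash of `(seed, read_id)` mapped to [0, 1): reproducible read by
read, independent of input order, and uniform (checked at 10,000 reads to
within ±2%). The mechanism (a keyed hash rather than a shared RNG stream)
is a package choice; only the policy is inherited.

Accumulated mismatch percentage across mapped reads is reported as a QC
metric, *not* applied as a filter — it is an observation about data
quality (typically below 0.75% for semiconductor amplicon runs), and the
synthetic runs reproduce that level from their 0.5% substitution error
rate.

### What the aligner oracle does and does not show

The brute-force oracle in the tests enumerates all ungapped placements
plus all placements with a single gap run (up to 3 bases). Because a gap
base and a mismatch cost the same here (−11 net), optimal glocal
alignments of *random* (non-homologous) reads routinely use several
separate gap runs, so that enumeration is a lower bound with equality
certified when the DP optimum is gapless or single-gap. Full equality is
checked two other ways: exhaustive edit-path enumeration on tiny cases,
and an independent implementation (`Biostrings::pairwiseAlignment`,
global-local, linear gap) across 500 random/planted pairs.

## Quantification

A mapped hit counts toward a locus iff its reference span overlaps the
locus interval by at least `min_overlap` (default 0.9) of the aligned
span; membership of boundary-spanning reads is otherwise undefined, so
the fractional rule makes the edge case explicit and tunable.
Strand is ignored (cDNA amplicons read from either strand). Hits
overlapping no locus are tallied off-target; counts conserve reads per
sample (`mapped = on_target + off_target`).

Relative frequency is `100 * count / denominator`. The default
denominator is the on-target total (columns sum to exactly 100); an
`all_mapped` denominator is available by flag. On well-behaved data the two are
nearly identical (≥99.85% of mapped reads fall in the counted loci, a
level the synthetic runs reproduce); both are retained so either
convention can be matched, and the choice is logged in the manifest.

The low-count rule excludes a locus when **more than** 50% of samples have
fewer than 1 raw count — strictly more, so zeros in exactly half the
samples retain the locus.

## Group statistics

*Fold change* `x` is the ratio of group **median** frequencies
(case/control). Zero medians follow fixed conventions: both zero → `x = 0`;
control zero with case positive → infinite, reported as a sentinel and
excluded (with a count) from summaries, since the transform below does not
cover it.

*Relative fold change* is the symmetric deviation from 1: `x - 1` above 1,
`1/x - 1` below 1, and 0 at both `x = 1` and `x = 0` (the zero rule is part
of the transform's definition). It satisfies `rfc(x) = rfc(1/x)`. Summaries
report both signed (sign from the direction of `x`) and absolute centers
and spreads, since aggregate figures of either kind appear in practice;
the "unchanged" window `0.8 < x < 1.2` is a reusable subset rule rather
than a hard-coded locus list.

The *differential-expression test* is a deliberately simplified
negative-binomial Wald test on raw counts: median-of-ratios size factors
(normalized to geometric mean 1, with a logged library-size fallback when
no locus is complete), per-locus method-of-moments dispersion pooled
across the two groups with a floor of 1e-8, and a Wald statistic
`log2FC / se(log2FC)` from the delta method on group means of normalized
counts. There is **no** empirical-Bayes dispersion shrinkage and no
outlier handling: the simplifications are the point, and they are tested
for calibration by simulation. When a group mean is zero, +0.5 is added to
both group means — the transparent fallback in place of shrunken
estimators.

One calibration choice deserves emphasis: with the study's group sizes
(4–8 per group) the large-sample normal reference for the Wald statistic
is noticeably anticonservative (empirically ~0.10 type-I error at
nominal 0.05 with n = 4 + 4, and spurious FDR discoveries in every null
run, because the statistic behaves like a t with few degrees of freedom).
The package therefore refers the statistic to a t distribution with
`n1 + n2 - 2` degrees of freedom, which coincides with the normal as n
grows. Under the package's calibration fixture (2000 loci × 8 samples,
log-normal means around 100, NB dispersion 0.05 — "moderate" for bulk
amplicon data) this gives type-I ≈ 0.05, essentially no null FDR
discoveries, and >80% power for a planted 4-fold effect at n = 4 vs 4.
Those fixture settings are fixed in the test suite; the numbers above are
recomputed by the tests themselves.

BH adjustment is the standard step-up procedure (via `stats::p.adjust`),
cross-checked in tests against the brute-force definition
`min over j >= i of m p_(j) / j`.

## qPCR module

The 2^-ddCt estimator assumes 100% amplification efficiency; efficiencies
are config metadata only (validated 90–110% upstream in practice, with
standard-curve fitting out of scope). Two reference genes are combined by
the arithmetic mean of their Cts, equivalent to normalizing expression by
their geometric mean. Averaging Cts first and averaging per-gene ddCt
results differ slightly; the Ct-mean rule is the package's documented
choice. The calibrator is
the mean (or, selectable, the median) control-group dCt. Replicate
triplicates are gated at SD < 0.2 cycles (strictly; a 1e-9 numeric
tolerance guards the boundary). The no-RT check passes when the RT+
signal is at least 10-fold the RT− signal, i.e. `2^(Ct_RT- - Ct_RT+) >= 10`,
with an undetected RT− reaction passing by convention.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the statistical
structure the analysis assumes, standing in for clinical samples that are
not publicly deposited:

* ~27 copies of a 600 bp consensus core, each diverged by 2–8%
  substitutions, flanked by realized primer sites carrying 0–2 planted
  mismatches (never in the protected 3' bases), embedded on random strands
  across 3 chromosomes of random background;
* neighbouring loci are spaced at least `min_locus_gap` (default 2001 bp,
  just above the scan's amplicon window) so the locus set recovered by
  in-silico PCR is exactly the planted truth;
* baseline proportions with one dominant locus (~48% of reads), a second
  at ~7.5%, a mid tier (log-uniform 1.66–5%) and a long tail (log-uniform
  0.01–1.66%), normalized — mirroring the observed frequency structure of
  such surveys and exercising both the low-count filter and
  rare-locus fold-change behaviour;
* planted case-group effects on rarer loci, with baseline proportions
  log-uniform in 0.5–3% (differentially expressed copies in such surveys
  sit in that band; a planted effect on a 0.01% locus would be both
  unrealistic and powerless at desk scale);
* per-sample totals of 5000 reads by default (a production depth of
  ~70,694 ± 24,812 is available as the `full_depth` preset with NB
  overdispersion on totals), read lengths uniform 140–180 nt,
  substitution errors at 0.005/base and homopolymer-biased indels at
  0.001/base (duplication/deletion, 4× weight inside runs) — the error
  profile of the semiconductor sequencing the workflow targets;
* every read id encodes `sample|locus|index` so any stage can be audited
  against the truth.

What the generator does **not** emulate: quality-score realism beyond a
flat placeholder, chimeric/PCR-duplicate reads, cross-sample barcode
bleed, and genuine biological covariance between loci (per-sample counts
are multinomial given the group proportions). Passing tests therefore
demonstrate the correctness and calibration of the *pipeline*, not the
robustness of the laboratory assay to those artifacts.

## Numerical and degenerate-input choices

* Fold-change zeros and infinities follow the conventions above; the
  comparison table flags filtered loci instead of dropping rows.
* Frequencies for a sample with a zero denominator are `NA` (undefined),
  never 0, with a warning.
* Ties in locus assignment (a hit passing the overlap threshold for two
  overlapping loci) go to the larger overlap, then to locus order.
* The DP traceback prefers substitutions over gaps at equal score, making
  reported mismatch/gap tallies deterministic.
* All randomness is seeded; per-read tie draws are keyed hashes, so they
  are independent of read order and stable across runs.

## Problem sizes used by the test suite

End-to-end checks run at 5000 reads × 8 samples (≈35,000 mapped reads
against a ~78 kb genome, about 30 s); the DE calibration fixture uses
2000 null loci × 8 samples plus 50 seeds of a 27-locus planted design;
determinism checks run a compact 800 reads × 4 samples configuration
twice. These sizes were chosen to make the full suite a coffee-break run
while keeping every statistical check at its stated operating point.

## Known limitations

* The NB test's dispersion is per-locus method-of-moments: with 2–3
  samples per group its estimates are noisy, and the t reference absorbs
  only part of that; very small designs (n = 2 vs 2) remain approximate.
* The seeded mapper's completeness guarantee is tied to the acceptance
  budget; lowering `min_accept_score` far below the default without
  raising `n_chunks` voids the guarantee (documented on `map_reads()`).
* `fold_change` medians make no multiplicity or pairing adjustments; they
  are descriptive statistics, with inference delegated to the NB test.
* The qPCR module models relative quantification only — no standard
  curves, efficiencies or melt analysis.
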