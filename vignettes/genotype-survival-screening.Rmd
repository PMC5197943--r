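---
title: "Genotype-stratified survival screening with dmetsurv"
author: "dmetsurv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-stratified survival screening with dmetsurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmetsurv)
```

## The problem

Drug-metabolism genotyping panels report one call per SNP probe per
patient: an unordered allele pair over `{A, C, G, T, -}` such as `A/G`, or
a special symbol (`NoCall`, `ZeroCopyNumber`, `RareAllele`, ...) when no
usable genotype was obtained. Clinical follow-up adds, per patient, an
overall-survival (OS) time and a progression-free-survival (PFS) time in
months, each with a status flag (1 = event observed, 0 = censored), plus an
optional binary response annotation. `dmetsurv` screens every probe of such
a matrix for association between genotype and survival, for both endpoints.

The data container is `OSDataset`, a `SummarizedExperiment` whose single
assay is the raw character matrix of calls and whose `colData` holds the
clinical records. This gives the "one clinical record per patient, linked
to all 1936 calls" structure directly: groupings store only sample
identifiers, and survival data are pulled from `colData` at analysis time
(`survivalData()`), so clinical values are never duplicated per probe and
an edit to a record is visible through every grouping.

## Per-probe grouping

`normalizeGenotype()` maps raw calls to a canonical form: trimmed,
upper-cased, alleles sorted in the fixed order `-`, `A`, `C`, `G`, `T`
(so `G/A` and `A/G` coincide as `A/G`). Anything that is not an allele
pair — the special symbols above (the vocabulary is configurable, as
genotyping pipelines extend it), empty cells, arbitrary junk — is
non-analyzable. At each probe, non-analyzable samples and samples lacking
a usable time/status for the chosen endpoint are excluded *from that probe
only*; this maximizes usable data and keeps a stray `NoCall` from deleting
a patient globally. A biallelic probe therefore yields at most three
groups (the two homozygotes and the heterozygote); probes with more than
two observed alleles are grouped faithfully without enforcing the bound.

## Survival estimation and comparison

Everything downstream uses three estimators implemented in the package
(the `survival` package appears only in the test suite, as an independent
oracle):

* **Kaplan–Meier product limit.** At the i-th distinct event time $t_i$,
  with $d_i$ events among $r_i$ subjects at risk,
  $\hat S(t) = \prod_{t_i \le t} (1 - d_i/r_i)$. Ties between events and
  censorings at the same time are resolved by the standard product-limit
  convention: events first, so subjects censored at $t_i$ still count in
  $r_i$. The curve is flat after the last observation. The median is the
  *smallest event time with* $\hat S(t) \le 0.5$ (boundary included, with
  a $10^{-9}$ numerical guard so an exact 0.5 computed in floating point is
  recognized); when the curve never reaches 0.5 the median is "not
  reached", exported as `NR`.

* **Mantel–Cox log-rank test.** At each distinct pooled event time the
  expected events in group $g$ are $d\, r_g/r$; the two-group statistic is
  $(O_1-E_1)^2/V$ with the hypergeometric variance, and the $k$-group
  statistic is the quadratic form of the first $k-1$ components of $O-E$
  against the corresponding variance submatrix ($k-1$ df). P-values come
  from the asymptotic upper chi-square tail, with no continuity
  correction. A singular variance submatrix (possible when one group's
  at-risk set vanishes early) is inverted by SVD pseudo-inverse; a
  comparison with zero events overall, or zero variance, is returned as a
  *flagged degenerate* result (statistic 0, p = 1) rather than an error, so
  a whole-matrix screen cannot crash on one pathological probe.

* **O/E hazard ratio.** $\widehat{HR} = (O_a/E_a)/(O_b/E_b)$ from the
  log-rank table. No proportional-hazards regression is fitted: the screen
  compares curve pairs without covariates, and the O/E form is computable
  from quantities the test already produces. The estimate is flagged
  undefined when any of the four terms is zero. Users should know this
  estimator is *attenuated for large effects*: in the package's own
  simulations at a true ratio of 4 its expectation is ≈ 3.6 (about 10%
  toward the null), within the tolerance used by the package's checks but
  worth remembering when effects are strong.

## Ranking

`rankProbes()` screens every probe for one endpoint. Per probe it reports
all genotype groups (size, events, median), the overall $k$-group test over
the *comparable* groups, and all $\binom{k}{2}$ pairwise tests with hazard
ratios. Two decisions here were genuinely open:

* **Ranking key.** Each probe produces several p-values (overall plus up
  to three pairwise). The ranking key is the **minimum non-degenerate
  pairwise p-value**: the screen's purpose is to surface probes where *some*
  genotype contrast is strong, and the per-pair significances are what the
  user inspects. The overall k-group p-value is reported alongside for
  transparency.

* **Minimum group size.** Default `minGroupSize = 2`: a single-sample
  group makes the variance term of the pairwise test nearly degenerate and
  its p-value uninformative. Groups below the threshold are still reported
  (size, events, median) but excluded from testing; setting
  `minGroupSize = 1` restores fully permissive behaviour. Probes with
  fewer than two comparable groups are *skipped*: listed separately, never
  ranked.

Raw p-values are ranked by default — the screen is hypothesis-generating,
and a default adjustment would silently change what users compare against
the literature. `adjustPvalues()` adds Benjamini–Hochberg or Bonferroni
values on request without reordering.

## The synthetic cohort generator

`simulateCohort()` draws a full OS-dataset with known ground truth. Its
defaults *are* the study conditions of the reference setting: **80
patients** on a **1936-probe** panel.

| parameter | default | meaning |
|---|---|---|
| `alleleFreq` | 0.3 | alternate-allele frequency; genotype classes follow Hardy–Weinberg $(1-q)^2, 2q(1-q), q^2$, giving the three-group structure naturally |
| `baselineHazard` | 0.03 /month | exponential death hazard; median ≈ 23 months, an advanced-cancer cohort |
| `progressionHazard` | 0.05 /month | independent progression process; PFS = min(progression, death), so PFS ≤ OS by construction |
| `censorRate` | 0.2 | drop-out is exponential with hazard $h_c = h_0\,c/(1-c)$, so with no follow-up cap the expected censored fraction equals `censorRate` exactly |
| `followupCap` | 60 months | administrative censoring |
| `specialSymbolRate` | 0.02 | cells overwritten by random special symbols |
| `seed` | — | identical configuration + seed ⇒ byte-identical files |

Causal probes multiply both hazards by a genotype-specific factor;
heterozygous calls are emitted in random allele order (`G/A` vs `A/G`) to
exercise normalization; times are rounded to 0.1 month, matching the
precision of clinical exports. `truthCheck()` closes the loop: top-k
recovery of causal probes and estimated-versus-true hazard ratios.

**What the generator does not emulate:** linkage disequilibrium between
probes (each probe is drawn independently), population structure,
covariate-dependent censoring, non-exponential (e.g. Weibull) hazards, and
informative missingness of calls. Passing tests therefore demonstrate the
*statistical machinery* — calibration, recovery, estimator agreement — not
robustness to correlated real-world genotype data; on a real cohort,
neighbouring probes in LD will rank together rather than independently.

## File formats and numerical conventions

The reader accepts tab-delimited, CSV (RFC-4180), and xlsx files in the
annotated-matrix layout (header of sample identifiers; clinical rows `OS`,
`Status-OS`, `PFS`, `Status-PFS`, `Response`; then probe rows). Labels are
matched case-insensitively with `-`, `_`, and spaces interchangeable,
because real exports vary. `Response` is optional (warning, not error); a
blank time or status excludes the sample from that endpoint only. Decimal
separator is the dot. Cells are preserved verbatim — normalization happens
at analysis time, never at parse time — and `writeOSDataset()` guarantees
cell-for-cell round trips (numeric values use R's shortest
round-trippable representation). xlsx reading takes the first worksheet
and rejects workbooks containing formula cells; xlsx writing emits a
minimal inline-string workbook. The tab dialect has no quoting convention,
so cells containing tabs or newlines are rejected rather than silently
corrupted.

Degenerate-input conventions, in one place: empty survival input is a
domain error; statuses outside {0, 1} are domain errors in the estimators
and *reported* (not thrown) by `validateOSDataset()`; a zero-probe dataset
yields an empty report; zero events overall yields a flagged degenerate
test; hazard ratios with a zero term are flagged undefined; ranking ties
are broken by probe identifier, making every report deterministic.

## Problem sizes used by the checks

The package's test suite and `scripts/acceptance.R` exercise: parsing at
the full 1936 × 100 scale (193,600 cells); the three-group bound over
10,000 random biallelic probe rows; estimator agreement with an
independent survival library over 1,000 random censored two-group
datasets (|ΔS| < 10⁻⁹, |Δχ²| < 10⁻⁶); type-I error of the two-group
log-rank over 2,000 null replicates (n = 40 + 40, ~20% censoring);
causal-probe recovery over 20 screens of 51 probes × 200 patients with
genotype hazard multipliers 1/2/4; and the O/E hazard-ratio estimate at
n = 2,000, averaged over 20 cohorts to remove Monte-Carlo noise (a single
cohort's estimate has sd ≈ 0.27 at a true ratio of 4, so averaging
isolates the estimator's systematic behaviour from draw noise). These
sizes were chosen as the smallest that make the corresponding binomial or
Kolmogorov–Smirnov bands informative.

## Known limitations

* The O/E hazard ratio is attenuated for strong effects (above); for
  effect *estimation* rather than screening, fit a Cox model downstream.
* The asymptotic chi-square p-value is anticonservative for very small
  groups; `minGroupSize` guards the worst case but 5-per-group comparisons
  remain approximate.
* Ranking by minimum pairwise p-value favours probes with three groups
  (three chances to be small) over two-group probes; the all-null
  behaviour of the screen is therefore *not* uniform on [0, 1] when group
  counts vary, which is why default output reports raw p-values plus
  optional FDR adjustment rather than claiming calibrated screen-level
  error.
* Genotype-dose (trend) tests, covariate adjustment, competing risks, and
  gene-level aggregation are out of scope.
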