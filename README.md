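# dmetsurv

Genotype-stratified survival screening for pharmacogenomic SNP matrices.

Pharmacogenomic panels such as the Affymetrix DMET chip report a genotype
call (an unordered allele pair like `A/G`, or a special symbol like
`NoCall`) for each of ~1936 ADME-gene SNP probes per patient. When such a
matrix is annotated with clinical outcomes — overall survival (OS) and
progression-free survival (PFS) times in months, each with an event/censor
status — a natural screening question arises: *at which probes do the
genotype groups differ in survival?* Answering it by hand means stratifying
patients probe by probe and comparing curves thousands of times.

`dmetsurv` automates that screen for clinicians and biostatisticians
working with genotype-annotated observational cohorts. For every probe it

1. normalizes the calls (`G/A` ≡ `A/G`), drops special symbols, and splits
   the samples into at most three genotype groups per biallelic probe;
2. estimates each group's survivor function with the Kaplan–Meier
   product-limit estimator
   `S(t) = Π_{t_i ≤ t} (1 − d_i / r_i)`,
   where `d_i` is the number of events and `r_i` the number at risk at the
   i-th distinct event time, and reports each group's median survival;
3. compares the groups with the Mantel–Cox log-rank test — overall across
   the k groups (χ², k − 1 df) and for every pair of groups — and estimates
   each pair's hazard ratio from the log-rank table,
   `HR = (O_a / E_a) / (O_b / E_b)`;
4. ranks all probes by significance (minimum pairwise p-value), separately
   for OS and for PFS, with optional Benjamini–Hochberg or Bonferroni
   adjustment.

A synthetic cohort generator with genotype-dependent exponential hazards,
random right-censoring, and known ground truth makes the whole pipeline
testable end to end, and a command-line interface (`screen`, `simulate`,
`plot`, `validate`) wraps the package functions for shell use.

## Worked example

The four fully printed samples of the reference layout (OS times 26.6,
15.7, 32.2, 2.3 months; statuses 1, 1, 0, 1) give the textbook product
limit:

```r
library(dmetsurv)
km <- kmEstimate(c(26.6, 15.7, 32.2, 2.3), c(1, 1, 0, 1))
km
#> KMCurve: 4 subjects, 3 events, 1 censored
#>  time n.risk n.event survival
#>   2.3      4       1     0.75
#>  15.7      3       1     0.50
#>  26.6      2       1     0.25
medianSurvival(km)
#> [1] 15.7
```

Each event removes one of the remaining at-risk subjects (4, then 3, then
2), so survival steps down through 0.75, 0.50, 0.25; the censored subject
(32.2 months) leaves the curve height unchanged. The median is the first
event time at which `S(t)` reaches 0.5, here 15.7 months.

A whole-matrix screen on a simulated cohort with one planted causal probe
(genotype hazard multipliers 1/2/4 at probe 42):

```r
cfg <- cohortConfig(nSamples = 80, nProbes = 200,
                    causalProbes = list(list(probe = 42,
                                             multipliers = c(1, 2, 4))),
                    seed = 11)
sim <- simulateCohort(cfg)
rep <- rankProbes(sim$dataset, "OS")
rep
#> RankedReport (OS): 200 ranked, 0 skipped probes
#> top probes:
#>  probe_id       rank_p
#>  AM_00073 0.0002980141
#>  AM_00111 0.0003328085
#>  AM_00042 0.0009715635
#>  AM_00154 0.0029662284
#>  AM_00090 0.0035931703
truthCheck(rep, sim$truth, topK = 5)$recovery
#> [1] 1
```

The planted probe `AM_00042` reaches rank 3 of 200 at this cohort size —
at n = 80, two null probes happen to beat it, a realistic reminder that an
unadjusted genome-wide screen is hypothesis-generating. Each ranked probe
carries its per-genotype group sizes, event counts and medians, the
overall k-group test, and all pairwise log-rank p-values and hazard
ratios:

```r
rep@results[[1]]
#> ProbeResult: AM_00073 (OS)  rank p = 0.000298
#>  genotype size events median comparable
#>       G/G   41     36   14.1       TRUE
#>       G/T   30     23   17.2       TRUE
#>       T/T    7      7    2.5       TRUE
#> pairwise:
#>  groupA groupB statistic       pValue hazardRatio
#>     G/G    G/T  1.243935 0.2647139849   1.3425369
#>     G/G    T/T 11.091225 0.0008673715   0.2843048
#>     G/T    T/T 13.082835 0.0002980141   0.2491474
```

`exportReport()` writes the ranking as TSV/CSV/JSON (one row per pairwise
comparison, medians `NR` when not reached), and `plotProbeKM()` draws the
per-genotype step curves with censor tick marks. From a shell:

```sh
./exec/dmetsurv screen --input cohort.txt --out reports/ --adjust bh
./exec/dmetsurv plot --input cohort.txt --probe AM_00073 --endpoint os \
    --out curve.pdf
```

## Vignette

`vignettes/genotype-survival-screening.Rmd` documents the statistical
model, every tunable parameter, the generator's assumptions and
limitations, and the package's numerical conventions.
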