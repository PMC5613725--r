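# hrvrqa

Recurrence quantification analysis (RQA) of RR-interval tachograms, for
researchers studying heart-rate variability (HRV) — in particular the
recovery of autonomic control after heart transplantation, where the
denervated heart starts out with an almost linear tachogram and regains
variability and complexity as re-innervation proceeds.

## What it computes

From a series of RR intervals (ms), the package builds the delay embedding
`v_i = (x_i, x_{i+τ}, …, x_{i+(m−1)τ})` and the recurrence matrix
`R_ij = 1{ ||v_i − v_j|| ≤ ε }`, then quantifies its structure:

| measure | meaning |
|---|---|
| %REC | percentage of recurrent cells |
| %DET | recurrent points on diagonals of length ≥ 2 (predictability) |
| Lmean / Lmax | mean / longest diagonal line (beats) |
| ENTR | Shannon entropy (bits) of the diagonal-length distribution |
| %LAM / TT | vertical-line analogues (laminar, "trapped" states) |

plus sample entropy SampEn(m, r) = −ln(A/B), the conditional probability
that templates matching for m beats still match for m + 1.

The radius is interpreted as a **percentage of the mean embedded distance**
(`radius = 70` → ε = 0.70·mean(d)), the convention of the classic
visual-recurrence-analysis tools, which makes the measures scale-invariant.
Defaults (m = 10, τ = 1, radius 70, minimum line 2, 1000-beat windows,
SampEn(2, 0.2·SD)) reproduce the published benchmark table for four model
series — random, chaotic (logistic map), periodic, linear (primes) — to
within a fraction of a percentage point; see the methods vignette
(`vignettes/rqa-hrv-methods.Rmd`) for the calibration and its two reported
residuals.

Around the core: RR-file ingestion (plain and Polar-HRM-style dialects), the
two-stage artifact filter with the strict "> 95% regular beats" acceptance
rule, recurrence-plot rendering to PNG, a synthetic transplant-cohort
simulator, and the extreme-quartile comparison (t-test or Mann–Whitney,
chosen by Shapiro–Wilk) relating each variable to months post-transplant.

## Worked example

```r
library(hrvrqa)

# the chaotic benchmark: logistic map x0 = 0.2, r = 3.7, 521 points
rqa_series(gen_logistic_series(521))
#> <rqa_result (n = 512)>
#>   %REC 20.0  %DET 96.5  Lmean 7.961  Lmax 82
#>   ENTR 4.111  %LAM 0.8  TT 3.206
```

512 embedded vectors (521 − 9); 20% of cell pairs are closer than 70% of the
mean distance; 96.5% of those recurrences sit on diagonals ≥ 2 beats, i.e.
the orbit is deterministic, but the longest parallel stretch is only 82
beats — short-range predictability, long-range divergence: chaos.

```r
# simulate a 40-recording transplant cohort and test the clinical hypothesis
sim <- gen_transplant_cohort(cohort_sim_config(n_patients = 40, seed = 7))
tab <- cohort_rqa_table(sim$tachograms)
compare_extreme_quartiles(tab, "lmean")
#> <quartile_comparison: lmean>
#>   cutoffs: Q1 <= 5.067, Q4 >= 5.574
#>   follow-up Q1: 92.36 +/- 23.07 months (median 98.01, n = 10)
#>   follow-up Q4: 16.22 +/- 9.80 months (median 13.61, n = 10)
#>   t_test, two-sided P = 4.992e-07
```

Recordings in the lowest Lmean quartile (short diagonal lines = complex
dynamics) average 92 months post-transplant; the highest quartile (long
lines = near-linear tachograms) averages 16 months: diagonal structure
shortens as re-innervation restores complexity. The SampEn comparison runs
in the opposite direction (high SampEn ↔ long follow-up), as expected.

End-to-end runs (ingestion → RQA/SampEn → quartile report, with a JSON run
log) go through `run_pipeline()`; `inst/cli/rqa-pipeline.R` wraps it for
shell use.

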