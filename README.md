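# bcpgenomics

Comparative genomic analysis of breast cancer diagnosed during pregnancy
(BCP) versus matched non-pregnant controls, as a tested, reusable R
pipeline.

## What it does, and for whom

Studies of pregnancy-associated breast cancer integrate whole-genome
mutation calls, copy-number arrays, expression profiles and survival
follow-up to ask whether pregnancy reshapes tumor biology. The patient-level
data behind such studies are controlled-access, so the analyses are hard to
reproduce or reuse. This package re-implements the full analytical layer for
analysts working on case-control tumor genomics:

* **Mutation burden** — non-silent classification, per-sample burden
  metrics, the ≥5% co-mutation table, group comparison by Mann-Whitney plus
  covariate-adjusted nested-model tests, and intra-tumor heterogeneity via
  the MATH score
  `MATH = MAD(VAFs) / median(VAFs)` (raw MAD, no scaling constant).
* **Mucin family analysis** — carrier status with MUC4/MUC16 exclusion,
  protein-position hotspots, serine-gain classification of missense changes,
  and two seeded Monte-Carlo enrichment tests (serine gain conditioned on
  the observed substitution spectrum; known-variant overlap), with the
  (1+k)/(1+N) empirical p estimator. The MUCsig metagene is the
  cohort-standardized mean mucin expression.
* **Mutational signatures** — 96-channel trinucleotide spectra in pyrimidine
  convention and exposure refitting by non-negative least squares with a 6%
  discard-renormalize step, presence calls, and the signature-20 (MMR
  deficiency) association suite: Spearman exposure-load correlation, MSH2
  expression and MSH2 deletion tests.
* **Copy-number QC and summaries** — MAPD and median lag-1 autocorrelation
  with the 0.30 / 0.5 failure thresholds, a CCF ≥ 30% gate, fraction of
  genome altered, arm-level frequency comparison with BH-FDR, gene-level
  deletion calls from length-weighted mean log2.
* **Survival** — Kaplan-Meier curves and medians (first time S(t) ≤ 0.5),
  log-rank, and Cox models (Efron ties) adjusted for age, date of
  diagnosis, stage, and IHC subtype.
* **Synthetic cohorts** — a deterministic generator that reproduces the
  published group structure (burden medians 20 vs 12, mucin carrier
  prevalence 45.7% vs 11.1%, serine-gain fraction 40.9%, signature-20
  prevalence 37.1% coupled to SNV load, MSH2 deletions 33.3% vs 2.6%,
  DFS/OS hazard ratios 1.81/2.53 with KM DFS medians 9.8/12.5 years), with
  ground truth for recovery testing.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, and `autoplot()` for curves and
exposures. See the methods vignette
(`vignettes/bcp-comparative-genomics.Rmd`) for the models, calibrations and
their assumptions.

## Worked example

Simulate a cohort at the study's size (35 BCP + 18 controls) and run the
core comparisons:

```r
library(bcpgenomics)
library(dplyr)

co <- simulate_cohort(cohort_params(seed = 1))

metrics <- summarize_catalogs(co$mutations, co$vafs) |>
  select(-n_snv, -n_indel) |>
  left_join(select(co$truth, patient_id, n_snv, n_indel), by = "patient_id")
burden_comparison(metrics, co$clinical, "n_nonsilent")
#>        metric median_bcp median_control    p_value adjusted_p
#> 1 n_nonsilent         24             11 0.02534583  0.2267504

cs <- carrier_status(co$mutations, co$clinical)
round(tapply(cs$carrier, cs$group, mean), 3)
#>     BCP control
#>   0.543   0.111

mm <- filter(co$mutations, gene %in% mucin_family(),
             consequence == "missense")
mc_serine_test(mm, n_draws = 9999, seed = 2)
#>   observed n_draws p_value null_mean
#> 1       13    9999   1e-04  3.269027
```

At this sample size the BCP excess of non-silent mutations (median 24 vs 11,
Mann-Whitney p = 0.025), the mucin carrier enrichment (54% vs 11%), and the
serine-gain excess (13 of 34 mucin missense mutations, Monte-Carlo
p = 1e-4, versus ~3.3 expected under the spectrum-conditioned null) are all
visible; the covariate-adjusted burden p is unstable at n = 53, as expected.
Survival contrasts need more patients to stabilize — at 500 per group:

```r
co2 <- simulate_cohort(cohort_params(n_bcp = 500, n_control = 500, seed = 1),
                       stages = "clinical")
cl <- mutate(co2$clinical, date_num = as.numeric(date_of_diagnosis),
             group = factor(group, levels = c("control", "BCP")))
km_logrank(cl$dfs_time, cl$dfs_event, cl$group)
#> Kaplan-Meier comparison
#> # A tibble: 2 × 2
#>   group   median
#>   <chr>    <dbl>
#> 1 BCP       10.0
#> 2 control   12.2
#> Log-rank: chi-square = 6.562 (df 1), p = 0.01042
```

The KM medians approach the calibrated 9.8 / 12.5-year targets, and the
crude contrast is smaller than the adjusted hazard ratio because the
generator gives BCP a protective stage profile (see the vignette).

The whole analysis can also be driven from one config:

```r
report <- run_pipeline(list(seed = 1, simulate = list(n_bcp = 35, n_control = 18)))
report$summary$mucin$carrier_freq_bcp
```

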