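# hnfscore

Gene-signature scoring and outcome association for
gastrointestinal-transcriptome-positive castration-resistant prostate
cancer (CRPC).

A subset of CRPC aberrantly expresses a gastrointestinal (GI) lineage
program driven by the transcription factors HNF1A and HNF4G; these tumors
respond poorly to androgen-receptor signaling inhibitors (ARSI) such as
enzalutamide. `hnfscore` implements the quantitative toolkit around this
biomarker for translational researchers:

* **HNF score** — for a genes × samples matrix on the log2(TPM + 1) scale,
  each gene is z-scored across the cohort, `z_gs = (x_gs − x̄_g) / sd_g`
  (sample sd), and a sample's score is `Σ_g z_gs` over the fixed 11-gene
  panel *HNF1A*, *HNF4G*, *AKR1C3*, *ANG*, *APOH*, *CLRN3*, *GAS2*,
  *METTL7B*, *MUC13*, *SGK2*, *UGT2B15*. Samples with sum-z ≥ 12 are
  **High**, ≤ 0 **Low**, otherwise **Intermediate**. An **AR score** uses
  the same construction over a combined androgen-receptor target panel.
* **Outcome statistics** — two-sided Fisher's exact test (hypergeometric
  summation), Kaplan–Meier product-limit curves with median survival,
  k-group log-rank (Mantel–Cox) test, Pearson correlation with t-based
  p-values.
* **Single-cell scoring** — counts-per-10k/log1p normalization, per-cell
  sum-z signature scores with a pooled z-reference, pseudobulk
  aggregation, Welch-t condition comparisons.
* **IHC quantification** — 0–300 H-scores from nuclear stain-intensity
  counts (`100 · (%weak + 2·%moderate + 3·%strong)`), region averaging,
  positive-cell fractions.
* **Xenograft growth metrics** — caliper volume `(D·d·h)/6`, per-animal
  fold change versus day 0, treated/vehicle arm ratios.
* **Synthetic data** — generators for response cohorts with a latent
  HNF-high class, two-condition single-cell experiments with a planted
  HNF suppression, score-linked IHC panels, and exponential tumor-growth
  curves, all pure functions of their parameters and a seed.

See `vignettes/hnf-score-methods.Rmd` for the model, the design decisions
and what the synthetic benchmarks do and do not demonstrate.

## Worked example

Score and stratify a synthetic 25-patient ARSI cohort, then associate the
High-vs-rest split with response and time on treatment:

```r
library(hnfscore)

cohort <- simulate_bulk_cohort(cohort_spec(), seed = 7)
scores <- score_signatures(cohort$matrix,
                           list(hnf_signature(), ar_signature()))
strat  <- stratify_hnf(scores[scores$signature == "HNF", ])
table(strat$stratum)
#>         High Intermediate          Low
#>            5            0           20

m    <- merge(strat, cohort$outcomes, by = "sample")
high <- m$stratum == "High"
nr   <- m$response == "nonresponder"
fisher_exact_2x2(sum(high & nr), sum(high & !nr),
                 sum(!high & nr), sum(!high & !nr))
#> <fisher_exact> p = 0.004743
#>      [,1] [,2]
#> [1,]    5    0
#> [2,]    5   15

logrank_test(m$tot_time, m$tot_event, droplevels(m$stratum))
#> <logrank_test> chi-square = 2.371 on 1 df, p = 0.1236

median_survival(km_estimator(m$tot_time[high], m$tot_event[high]))$median
#> [1] 4.441242
```

The cohort planted 5 latent HNF-high samples among 25; stratification at
the fixed thresholds recovers all five (scores 14.6–20.2 versus ≤ −1.3 for
the rest), all five are enzalutamide nonresponders (exact p = 0.0047), and
the High stratum's median time on treatment is 4.4 months. On the published
response table itself (High: 4 nonresponders / 1 responder; Low: 3 / 17)
the same test gives:

```r
fisher_exact_2x2(4, 1, 3, 17)$p.value
#> [1] 0.01225296
```

`run_pipeline()` wraps the whole flow (file input → scores → stratification
→ Fisher + KM/log-rank → TSV/JSON outputs with a reproducibility manifest).

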