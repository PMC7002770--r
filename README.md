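# hypoxscan

Tumour hypoxia — inadequate oxygenation of the tumour
microenvironment — is a hallmark of aggressive disease. Because direct
oxygen measurements are rarely available for sequencing cohorts,
hypoxia is routinely estimated from bulk mRNA abundance with published
gene-expression signatures. `hypoxscan` implements that estimation and
the downstream association machinery for pan-cancer cohorts:

* **Scoring** — for each signature gene, tumours in the top 50% of the
  cohort's abundance for that gene vote `+1`, the rest vote `-1`; a
  tumour's hypoxia score is the sum of votes over the signature
  (`compute_hypoxia_scores()`). Utilities cover per-cancer-type
  summaries, the `[-1, +1]` rescaling of medians, Spearman/AS89
  signature concordance, tumour-vs-normal rank-sum comparisons and
  median dichotomization into hypoxic/normoxic classes.
* **Feature tables** — driver event status (SNV/CNA/SV, with multiple
  classes in one gene collapsed to *compound*), mutational-signature
  exposure proportions, monoclonal/polyclonal classification from
  subclonal reconstructions, and an inner-joined analysis table
  (`assemble_feature_table()`).
* **Mixed-model association engine** — for a feature *x* of tumour
  *i* in cancer type *c*, the full model

  `hypoxia_i = β₀ + β₁ x_i + β₂ purity_i + β₃ age_i + β₄ sex_i + u_c + ε_i`,
  `u_c ~ N(0, σ²_α)`, `ε_i ~ N(0, σ²_ε)`

  is compared to the null model without *x* by a maximum-likelihood
  likelihood-ratio test (`fit_lmm()`, `lrt_compare()`). Effect sizes
  are reported as marginal/conditional R²
  (`nakagawa_r2()`): `R²_M = σ²_f / (σ²_f + σ²_α + σ²_ε)` and
  `R²_C = (σ²_f + σ²_α) / (σ²_f + σ²_α + σ²_ε)`, with σ²_f the variance
  of the fixed-effect predictor. Simulation-based scaled residuals
  (`simulated_residuals()`) check model adequacy; `adjust_pvalues()`
  provides Bonferroni and Benjamini–Hochberg control, applied per scan
  (Bonferroni below 20 tests, BH FDR otherwise).
* **Scans and special tests** — `run_association_scan()` over feature
  panels after a ≥15-samples-per-type filter, an independence test with
  an extra adjuster (`run_independence_test()`), and a
  hypoxia-by-driver interaction test on tumour clonality
  (`run_interaction_test()`).
* **Synthetic cohorts** — `generate_cohort()` draws a multi-cancer
  cohort from a known generative world (latent hypoxia axis,
  cancer-type random intercepts, planted slopes, logistic driver links,
  Dirichlet-multinomial exposures, a planted clonality interaction), so
  every stage is testable without access-controlled data.

## Worked example

```r
library(hypoxscan)

cfg    <- sim_config(n_cancer_types = 6, samples_per_type = 40, seed = 42)
cohort <- generate_cohort(cfg)
scores <- compute_hypoxia_scores(cohort$expression, cohort$signatures$buffa,
                                 sig_name = "buffa")
head(scores, 3)
#>   sample signature score n_genes_used
#> 1 SP0001     buffa   -18           52
#> 2 SP0002     buffa    26           52
#> 3 SP0003     buffa    30           52
```

Scores range over ±52 (one vote per signature gene). Per-type medians,
interquartile ranges and the fraction of tumours with elevated hypoxia
(score > 0):

```r
summarize_scores(scores$score, cohort$covariates$cancer_type)
#>   cancer_type  n median  iqr fraction_elevated
#> 2        CT02 40      6 58.0             0.525
#> 6        CT06 40      4 45.5             0.550
#> 3        CT03 40     -3 53.0             0.475
#> 1        CT01 40     -5 40.5             0.450
#> 4        CT04 40     -5 61.5             0.450
#> 5        CT05 40     -8 51.0             0.425
```

Associate hypoxia with the planted deletion burden (the generator's
default world plants a hypoxia→deletions slope of 0.5):

```r
d <- cohort$covariates
d$hypoxia_score   <- scores$score
d$total_deletions <- cohort$features$total_deletions
run_association_scan(d, "total_deletions")
#> Association scan: 1 feature(s), 1 tested, correction = bonferroni
#>           feature         p     p_adj r2_marginal r2_conditional direction   n
#> 1 total_deletions 6.416e-07 6.416e-07      0.1523          0.179         1 240
```

The planted effect is recovered (LRT p = 6.4e-07, positive direction);
the feature explains ~15% of score variance through the fixed effects
(`r2_marginal`), rising to ~18% once cancer-type baselines are included
(`r2_conditional`).

## Command line

```sh
exec/hypoxscan simulate --config sim.json --out cohort/ --seed 17
exec/hypoxscan score    --expr cohort/expression.tsv \
                        --signatures cohort/signatures.gmt --out scores.tsv
exec/hypoxscan pipeline --config pipeline.json
```

Exit codes: 0 success, 2 validation error, 3 model-fitting error.

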