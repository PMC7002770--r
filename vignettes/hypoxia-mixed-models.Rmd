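---
title: "Hypoxia scoring and mixed-model association scans: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypoxia scoring and mixed-model association scans: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hypoxscan)
```

## The problem

Bulk RNA-seq cohorts spanning many cancer types carry a usable readout
of tumour oxygenation: genes in published hypoxia signatures shift
coherently with the microenvironment. `hypoxscan` turns that readout
into a per-tumour score and asks which genomic and evolutionary
features — mutational densities, driver gene status, mutational
signature activity, subclonal architecture — co-vary with it across
cancers, while acknowledging that every cancer type has its own
baseline for both hypoxia and genome instability. That last point is
why the engine is a mixed model rather than a pooled regression:
pooling 27 cancer types without a per-type term would let between-type
differences masquerade as hypoxia effects.

## Scoring conventions

For each signature gene present in the matrix, samples strictly above
the per-gene cohort median vote +1, all others −1; the score is the
summed vote. Three conventions are deliberate and fixed:

* **Ties at the median vote −1.** "Top 50%" leaves the tie side
  unstated; taking strictly-greater makes the rule deterministic and
  means ties never inflate a score. With an even number of samples and
  no ties, each gene's votes cancel exactly, so cohort scores sum to
  zero — a property the tests assert.
* **Scores are cohort-relative.** A tumour's score depends on which
  samples are scored together. Tumour-vs-normal comparisons therefore
  score tumours and normals of a tissue jointly; everything else scores
  tumours alone. The function interfaces keep this explicit: you pass
  the cohort you mean.
* **Quantiles are type 7** (linear interpolation), because
  interquartile ranges are reported per cancer type and the convention
  changes the printed value.

Only the *rank* of a sample within each gene matters, so any strictly
increasing transform of one gene's abundances (log, power,
normalization constants) leaves every score unchanged. Signature genes
missing from a matrix are skipped and counted in a logged warning —
fixed gene lists applied to heterogeneous matrices always lose a few
genes, and silent imputation would distort the parity and bound
invariants (|score| ≤ genes used; score ≡ genes used mod 2).

Median dichotomization classes samples strictly above the cohort median
score as hypoxic; a fully tied cohort is all-normoxic with a warning.

## Spearman concordance and AS89

Signature agreement is summarized by Spearman's ρ with a two-sided
p-value from algorithm AS89 on the statistic S = Σd². For tie-free
cohorts of n ≤ 9 the null distribution is enumerated exhaustively (n!
orderings); beyond that the AS89 Edgeworth expansion is used, with the
lower tail obtained from the symmetry of S about its mean. The
Edgeworth branch is an approximation: its error against the exact
distribution is about 10⁻² near n = 12, 10⁻³ near n = 20 and vanishes
by n ≈ 300 — the tolerances the test suite uses. At the small n where
the approximation is poor, the package is already in its exact branch;
the tests therefore check the exact branch against enumeration and the
Edgeworth branch against R's exact implementation at larger n.

## The mixed model

Every association fits

y_i = x_i'β + u_{c(i)} + ε_i,  u_c ~ N(0, σ²_α),  ε_i ~ N(0, σ²_ε)

with a single random intercept on cancer type. For a fixed variance
ratio λ = σ²_α/σ²_ε the covariance is block diagonal and β, σ²_ε
profile out in closed form (Woodbury), leaving a one-dimensional
deterministic search over log λ: a fixed 41-point grid bracketing,
golden-section refinement to 10⁻¹⁰, and an explicit comparison against
the boundary λ = 0, which reduces the fit to ordinary least squares and
is flagged (`boundary = TRUE`). There is no random initialization
anywhere, so fits are bit-reproducible. The implementation is validated
against `lme4` to ~10⁻⁶ in coefficients, variance components and
log-likelihood, in both ML and REML; the REML log-likelihood follows
the lme4 convention (it includes log|X'V₀⁻¹X|).

**LRTs use ML.** REML likelihoods are not comparable across different
fixed-effect structures, so full-vs-null comparisons refuse REML fits;
REML remains available for variance reporting. The LRT statistic is
floored at zero and referred to χ² with df equal to the difference in
fixed-effect count.

**R².** σ²_f is the sample variance of the fixed-effect linear
predictor over the analysis rows; marginal R² = σ²_f/(σ²_f+σ²_α+σ²_ε),
conditional adds σ²_α to the numerator. Conditional ≥ marginal always;
both are undefined (an error, not NaN) when the total is zero.

**Binary responses.** Clonality (0/1) is fitted with the same Gaussian
machinery — a linear probability model — because the analysis this
package reproduces ran its clonality interaction through the linear
mixed-model ANOVA. A logistic mixed model (`engine = "logistic"`, via
lme4) is exposed for sensitivity analysis. The linear-probability
choice is a faithful-reproduction decision, not a statistical
endorsement; with the moderate effect sizes of the synthetic world the
two engines agree (tested).

## Simulation-based residuals

`simulated_residuals()` draws `n_sim` complete response vectors from
the *fitted marginal* model — new random intercepts each draw
(unconditional simulation) — and scores each observation by the
proportion of simulated values below it, ties broken uniformly from the
seeded RNG stream. Correct specification makes each residual uniform on
[0, 1]; departures are tested by one-sample Kolmogorov–Smirnov and by a
Spearman trend against rank-transformed predictions.

Two caveats are documented rather than hidden. First, the alternative
scheme — simulating conditional on estimated random effects — answers a
different question (residual-level fit given the groups); the
unconditional scheme was chosen because it tests the whole generative
claim including the random-intercept distribution. Second, residuals of
observations sharing a group are positively correlated under
unconditional simulation, so the KS p-value is approximate. In
practice the fitted parameters absorb the realized group moments and
the test is near-nominal (slightly conservative) across the regimes the
acceptance suite covers, including intraclass correlations up to 0.5
with 20–27 groups; gross misspecification (t₂ residual truth, infinite
variance) is flagged essentially always at n = 500.

## Multiple testing

Each scan (densities; drivers; SBS exposures; ID exposures;
subclonality) is its own correction family, matching an analysis that
corrected per panel. The rule is mechanical: Bonferroni when the family
ran fewer than 20 tests, Benjamini–Hochberg step-up FDR otherwise; both
implemented directly and tested against a literal step-up oracle. SBS
and ID signatures default to separate families (they are reported as
separate panels); a caller can merge them by passing one combined
feature list.

Driver features mutated in fewer than 5 retained samples are skipped
with a log entry — a fit to 3 mutated tumours across 27 types estimates
nothing — and per-feature fit failures flag the record and let the scan
continue, so one degenerate feature cannot kill a panel.

## The synthetic world

`sim_config()` defaults state one generative world, chosen once:

| parameter | default | rationale |
|---|---|---|
| types × samples | 27 × 44 (n = 1188) | scale of the pan-cancer cohort the package targets |
| signature sizes | 52 / 99 / 32 | sizes of the three published hypoxia signatures |
| latent hypoxia | N(0, 1) per sample | continuous axis; the score is its observable estimate |
| expression effect | 1 (log2 shift / unit h), noise SD 1 | per-gene r ≈ 0.7; a 52-gene vote recovers h with ρ > 0.95 |
| feature model | αc + βh + 0.3·purity + 0.005·age + ε, τ = σ = 1 | matches the random-intercept structure the engine assumes |
| planted slope | total_deletions = 0.5 | one strong correlate, as in the motivating analysis |
| driver link | logit⁻¹(−0.85 + slope·h), PTEN 0.7, TP53 0.5 | ~30% baseline prevalence; hypoxia-enriched drivers |
| exposures | Dirichlet-multinomial, concentration 25, tilts exp(s·h) with SBS1 −0.4, SBS3 +0.4, ID6 +0.3 | counts conserve the tumour's total burden by construction |
| burden | NegBin(mean 5000, size 1.5) + 1 | heavy-tailed WGS mutation totals |
| clonality | logit⁻¹(−0.5 + 0.4·hyp + 0.4·drv + 1.5·hyp·drv) | planted interaction detectable at n = 1000 with power ≈ 0.9 |
| purity, age, sex | Beta(3.5, 1.5); integer U[20, 90]; Bernoulli(0.5) | typical consortium covariate ranges |

Randomness flows from one seed; each table draws from a substream at a
fixed offset, so adding a table never perturbs earlier ones and bundles
are byte-identical under a fixed seed.

What the generator does **not** emulate — and hence what a green test
does not establish: latent hypoxia has no cancer-type component (the
stated structure puts type effects on the *features*, not on h), so the
within-type variance fraction of synthetic scores is near 1, unlike
real cohorts where type explains half the spread; the 15 density
features are conditionally independent given h, with no attempt at the
real features' mutual correlation structure; expression has no
batch/library-size artifacts, no negative-control (down-regulated)
signature genes by default (the scorer supports signed genes, the
default world plants one direction); and no missing data. Calibration
and recovery results on this world are evidence about the machinery,
not about any real cohort.

## Numerical and design choices

* Optimizer: profiled log-likelihood over log λ on [−15, 15]; boundary
  declared when the λ = 0 likelihood is within 10⁻⁸ of the interior
  optimum. Variances at the boundary report exactly 0.
* The OLS-degeneracy acceptance test uses balanced groups sharing one
  covariate pattern: under that design V·X stays in the column span of
  X, so GLS equals OLS *exactly* for any estimated variance ratio, and
  the 10⁻⁶ agreement genuinely tests the GLS algebra rather than
  depending on the boundary estimate landing at zero.
* Configs, manifests and ground truth are JSON (`jsonlite`); tables are
  tab-delimited UTF-8 with a header; gene sets are GMT. JSON was
  preferred over YAML to keep the runtime dependency set to packages
  guaranteed in the deployment environment.
* Pipeline manifests contain no timestamps, so identical seed + config
  gives byte-identical output trees (tested by checksum).
* The acceptance-report script runs a reduced cohort (8 types × 30)
  purely for runtime; the full default world runs in the test suite.

## Known limitations

Single random intercept only — no crossed/nested effects or random
slopes, which the scans do not need but a finer analysis might. The
linear probability model can predict outside [0, 1] for extreme
covariates. The KS uniformity p-value is approximate under grouped
data (above). AS89's Edgeworth branch is an approximation for
10 ≤ n ≤ ~50 where neither enumeration nor asymptotics is ideal; its
error there (~10⁻³–10⁻²) is documented and tested, and is irrelevant at
cohort scale. The generator's conditional-independence assumption for
density features is a simplification flagged above, not an assertion
about real genomes.
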