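---
title: "Models and methods for CpG-island methylation heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for CpG-island methylation heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylhet)
library(dplyr)
```

This vignette documents the statistical models behind `methylhet`: what
each estimator computes, which assumptions it makes, why the synthetic
generators use the defaults they do, and where the generators are
knowingly unrealistic. The worked-code chunks use small problem sizes;
the sizes used throughout (2,000 regions, 50,000 amplicon reads, 10,000
ChIP windows, 1,000 CGIs for prediction) are this package's own choices,
picked so that Monte-Carlo error is small relative to the effects being
measured while everything runs in minutes on one CPU.

## 1. CpG island detection

A CpG island is defined by three sequence thresholds evaluated jointly:
GC fraction > 0.5, length > 200 bp, and observed/expected CpG ratio
> 0.6, where

$$\mathrm{obs/exp} = \frac{n_{CpG} \cdot L}{n_C \cdot n_G}.$$

`detect_cgis()` slides a 200-bp window in 1-bp steps (cumulative-sum
arithmetic, so the scan is linear time), merges overlapping qualifying
windows, and then trims each merged span from both ends until the span
*itself* passes all three thresholds, so every reported island is a
bona-fide island rather than just a union of qualifying windows.
Reported boundaries are exact up to the resolution of the window — a
span's edges can sit up to one window width from where a different
formulation would put them. Note that the union of *all* qualifying
substrings (any length) is not a usable definition: appending background
sequence to a dense island dilutes GC toward 0.5 only linearly, so
kilobase-scale marginal substrings qualify far outside any island; a
fixed scan window avoids that pathology.

Shores are the 2-kb flanks of each island with neighbouring islands
subtracted; promoters are TSS ± 500 bp, called HCP when they overlap an
island by at least 1 bp and LCP otherwise.

## 2. Coverage-weighted differential methylation

Per-CpG methylation estimates from bisulfite counts have precision
proportional to read coverage, so region-level tests weight CpGs by
coverage. For one condition with methylation values $x_i$ and weights
$w_i$:

$$\bar{x}_w = \frac{\sum w_i x_i}{\sum w_i}, \qquad
  n_\mathrm{eff} = \frac{(\sum w_i)^2}{\sum w_i^2}, \qquad
  s_w^2 = \frac{\sum w_i (x_i - \bar{x}_w)^2}{\sum w_i}
          \cdot \frac{n_\mathrm{eff}}{n_\mathrm{eff} - 1}.$$

The two-condition statistic is Welch's $t$ with
$s_w^2 / n_\mathrm{eff}$ standard errors and Welch–Satterthwaite
degrees of freedom computed from the effective sample sizes. With equal
weights this reduces *exactly* to `t.test()` (the suite asserts
agreement to $10^{-9}$). The approximation treats the weights as fixed
precision constants; it is well calibrated when coverage is moderately
dispersed, and anti-conservative coverage regimes are exactly what the
null-calibration checks monitor (see §7).

Multiple testing uses hand-rolled Storey q-values: $\hat\pi_0(\lambda)$
on the grid $\lambda = 0.05, 0.10, \ldots, 0.95$, smoothed with a
df-3 spline and read off at $\lambda = 0.95$; if fewer than 100 tests
are available or the estimate falls outside $(0, 1]$, the procedure
falls back to Benjamini–Hochberg ($\pi_0 = 1$). Regions failing the
minimum-data rule (fewer than 2 CpGs at ≥ 5× in either condition) are
excluded from the multiple-testing family rather than imputed.

```{r dmr}
sim <- simulate_rrbs_pair(sim_config(seed = 42, n_regions = 300,
                                     dmr_fraction = 0.1, dmr_effect = 0.3))
dmrs <- call_dmrs(sim$condition_a, sim$condition_b, sim$regions)
glance(dmrs)
```

## 3. The RRBS generator

`simulate_rrbs_pair()` draws, per region, a baseline methylation level
from Beta(2, 8); per CpG and condition, the site-level methylation is
the region baseline plus independent Gaussian jitter (sd 0.05, clipped
to [0, 1]); coverage is negative-binomial (mean 30, size 15, truncated
at ≥ 1); methylated counts are binomial. Planted DMRs shift condition
B's baseline by `dmr_effect`.

Why these defaults:

* **Beta(2, 8)** puts most regions at low methylation, which is where
  CpG islands live, and — importantly for recovery experiments — leaves
  room to add a +0.3 effect without saturating at 1, which would
  silently cap the observable effect size.
* **NB size 15 at mean 30** gives realistic ~30× RRBS coverage with
  moderate overdispersion. The weighted test's effective-sample-size
  approximation assumes weights are not too heavy-tailed; strongly
  overdispersed coverage (size ≲ 5) makes the null test anti-
  conservative, so the default regime is the one in which the test is
  honest — and the calibration check exists to catch drift.
* **Jitter sd 0.05** reflects biological site-to-site variability; it
  is the noise floor against which a 0.3 effect gives high power at
  10 CpGs per region.

Known limitations: jitter is i.i.d. across sites (no within-region
spatial autocorrelation beyond the shared baseline), coverage is
independent of methylation, there are no strand effects, no bisulfite
conversion failures, and regions are equally sized and equally spaced
on one synthetic chromosome.

## 4. Amplicon reads and methylation kinetics

`simulate_amplicon_reads()` produces per-molecule M/U patterns over a
locus of CpGs (default 50 sites, 8-bp spacing, susceptibility 0.2 per
site) under two kinetic models:

* **Distributive**: every site on every molecule is an independent
  Bernoulli draw — single, independent enzyme engagements.
* **Processive**: methylation arrives in *runs*. Each molecule receives
  $N \sim \mathrm{Poisson}(\mu)$ runs with uniform start sites and
  geometric lengths (mean 5 sites, truncated at the locus edge), where
  $\mu = -\log(1 - \bar{p})\, m / \ell$ is chosen so the expected
  per-site marginal matches the distributive model's $\bar p$. Shared
  runs make nearby sites positively correlated, and the correlation
  decays with distance — the observable signature of processivity.

Three read-level statistics summarize heterogeneity:

* **Epiallele counting** (`count_epialleles()`): the number of distinct
  complete patterns, overall and stratified by the number of methylated
  sites $k$ (bounded by $\binom{m}{k}$).
* **Per-read discordance** (`per_read_discordance()`): the fraction of
  reads (with ≥ 4 covered CpGs) that are neither fully methylated nor
  fully unmethylated. For independent sites with $p = 0.2$ and
  $m = 10$ the closed form is $1 - (0.8^{10} + 0.2^{10}) \approx
  0.893$, which the simulation reproduces to ±0.01 at 50,000 reads.
* **Phase correlation** (`phase_correlation()`): the Pearson (phi)
  correlation of the binary states of each CpG pair across the reads
  covering both, averaged in 25-bp distance bins. Constant sites are
  excluded and counted. Distributive reads give every bin ≈ 0;
  processive reads give a monotone distance decay.

```{r phase}
amp <- simulate_amplicon_reads(sim_config(seed = 7, amplicon_model = "processive"),
                               5000)
pats <- extract_patterns(amp$reads, amp$cpg_positions)
head(phase_correlation(pats, bin_width = 25), 3)
```

## 5. ChIP window enrichment

`poisson_enrichment()` models window read counts as Poisson with a
common background rate $\hat\lambda$ (the mean count, optionally
trimmed), and scores each window with the exact tail probability
$P(X \ge k) = \texttt{ppois}(k - 1, \hat\lambda, \mathrm{lower=FALSE})$,
followed by Storey q-values. Because the counts are discrete, the
p-values are *super-uniform* under the null (conservative, never
anti-conservative); for calibration diagnostics the `randomize = TRUE`
option returns the randomized p-value
$P(X > k) + U \cdot P(X = k)$, which is exactly uniform under the null
and is what the uniformity checks use. The enrichment flags of two
marks on a common anchor set combine into the four chromatin states
(`classify_cgi_states()`): H3K4me3-only, H3K27me3-only, bivalent,
neither.

The generator (`simulate_chip_windows()`) draws a 95/5 mixture of
background (λ = 10) and enriched (6× background) windows — rates at
which a correct implementation separates the classes nearly perfectly,
so recovery failures indicate bugs rather than hard statistics.

## 6. Predicting hypermethylation-susceptible CGIs

`build_feature_matrix()` assembles eight features per CGI: four signal
tracks (H3K4me3, H3K27me3, H3K36me3, DNase) as z-scores of
$\log(\mathrm{RPKM} + 0.001)$, after dropping (or winsorizing) CGIs
above each track's own 99th percentile, plus CpG density, normalized
CpG density, GC fraction, and control methylation; only CGIs with
control methylation < 0.2 (canonically unmethylated islands) are
retained, and filtering precedes normalization. Five classifier
backends are available — random forest (100 trees, class weights
1 : n₋/n₊), logistic regression, naive Bayes, a decision tree, and
gradient boosting (depth 10, 10 rounds, subsample 0.7, positive-class
weight n₋/n₊) — with the remaining parameters at library defaults.

Evaluation is stratified 5-fold cross-validation; out-of-fold scores
are pooled into one precision–recall curve, and `recall_at_fdr5` is the
recall at the highest-recall threshold with precision ≥ 0.95 (FDR =
1 − precision). `feature_ablation()` re-evaluates with each feature
removed using the *same* folds and seed, so ΔAUC-PR is a paired
comparison.

`simulate_feature_table()` generates feature tables with a realistic
correlation structure: a latent "openness" variable (loading 0.7)
drives H3K4me3 and DNase up and H3K27me3 and control methylation down,
and the label is Bernoulli with a logistic link whose intercept is
solved numerically so the realized prevalence matches the target.
Setting `openness_loading = 0` and a single-feature weight vector gives
a table where the label depends on exactly one feature — the
construction used to verify that ablation ranks that feature first.

```{r ablation}
ft <- simulate_feature_table(sim_config(seed = 101), 400,
                             weights = c(h3k4me3 = 2), openness_loading = 0)
ab <- feature_ablation(ft, method = "logistic", k = 5, seed = 1)
head(tidy(ab), 3)
```

## 7. Verification strategy

Every estimator is tested against an *independent* oracle implemented
with a different algorithm: weighted medians against the
integer-weight expansion, the weighted t-test against `t.test()` at
equal weights, q-values against `p.adjust(..., "BH")`, PR curves
against a brute-force threshold sweep, window counts against a read
loop, hypergeometric overlaps against exhaustive set enumeration, CGI
calls against naive per-substring window counting, and epiallele counts
against `unique()` on pattern strings. Simulation-level checks close
the loop: null RRBS data must be rejected at close to the nominal 5%
rate, planted DMRs recovered at high sensitivity and controlled FDR,
the discordance closed form reproduced, distributive phase correlation
flat and processive phase correlation decaying, randomized Poisson
p-values uniform, and ablation must identify a planted informative
feature. All generator defaults are frozen in `sim_config()`; analyses
are reproducible from a single seed.
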