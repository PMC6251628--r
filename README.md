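# methylhet

DNA methylation is usually summarized as a per-site average, but the
biology that matters often lives in the *heterogeneity* around that
average: which CpG islands (CGIs) gain methylation between two
conditions, whether individual DNA molecules carry coherent or scrambled
methylation patterns, and which chromatin features mark an island as
susceptible to aberrant hypermethylation. `methylhet` is a tidy R
toolkit for exactly these questions, built around CpG-island-centric
bisulfite sequencing:

* **Genome annotation** — CpG island detection from raw sequence
  (GC > 0.5, length > 200 bp, observed/expected CpG > 0.6, sliding
  200-bp windows), CGI shores, and HCP/LCP promoter classification.
* **Methylation quantification** — strand merging, coverage-weighted
  median methylation per feature and weighted-mean methylation per
  genomic tile, with explicit minimum-data rules (≥ 2 CpGs at ≥ 5×).
* **DMR calling** — a coverage-weighted Welch t-test with
  effective-sample-size degrees of freedom, Storey q-values
  (hand-rolled π₀ estimation with a BH fallback), and region-level
  differential calls with direction and effect-size thresholds.
* **Chromatin state** — Poisson-model ChIP-seq window enrichment,
  four-way H3K4me3/H3K27me3 (active/Polycomb/bivalent/neither)
  classification, and composite TSS profiles.
* **Epiallele analysis** — per-molecule methylation patterns from
  amplicon reads: distinct-epiallele counting, per-read discordance,
  and distance-binned phase correlation that separates distributive
  from processive methylation kinetics.
* **Hypermethylation prediction** — an eight-feature CGI predictor
  (z-scored log RPKM signal tracks plus sequence features) with five
  classifier backends, stratified cross-validated precision–recall,
  and paired per-feature ablation.
* **Synthetic data** — a seeded generator for two-condition RRBS
  counts, per-molecule amplicon patterns, ChIP window counts, and
  correlated CGI feature tables, always emitting ground truth *beside*
  the data, so every stage is testable end to end without external
  data.

All functions take and return tibbles, ship `tidy()`/`glance()`
methods, and have `autoplot()`/`plot_*()` companions.

## Worked example

Simulate a two-condition RRBS experiment with 10% planted DMRs at a
methylation difference of 0.3, and call DMRs:

```r
library(methylhet)
library(dplyr)

cfg <- sim_config(seed = 42, n_regions = 500, dmr_fraction = 0.1, dmr_effect = 0.3)
sim <- simulate_rrbs_pair(cfg)
dmrs <- call_dmrs(sim$condition_a, sim$condition_b, sim$regions)
glance(dmrs)
#> # A tibble: 1 × 6
#>   n_regions n_testable n_dmr q_thresh diff_thresh direction
#>       <int>      <int> <int>    <dbl>       <dbl> <chr>
#> 1       500        500    50     0.05         0.2 two_sided

tidy(dmrs) |> filter(is_dmr) |> arrange(q_value) |> head(3)
#> # A tibble: 3 × 15
#>   region_id    chrom   start    end n_cpgs_a n_cpgs_b mean_a mean_b  diff t_stat
#>   <chr>        <chr>   <int>  <int>    <int>    <int>  <dbl>  <dbl> <dbl>  <dbl>
#> 1 region_00197 chrSim 196000 196091       10       10 0.0546  0.464 0.410  -13.8
#> 2 region_00158 chrSim 157000 157091       10       10 0.101   0.401 0.300  -11.8
#> 3 region_00020 chrSim  19000  19091       10       10 0.128   0.488 0.360  -10.1
```

Because the generator emits ground truth alongside the data, recovery
is directly checkable — here all 50 planted DMRs are found with no
false positives:

```r
truth <- inner_join(tidy(dmrs), sim$truth, by = "region_id",
                    suffix = c("_called", "_true"))
summarise(truth,
          sensitivity = sum(is_dmr_called & is_dmr_true) / sum(is_dmr_true),
          fdr = sum(is_dmr_called & !is_dmr_true) / max(sum(is_dmr_called), 1))
#>   sensitivity   fdr
#> 1           1     0
```

Read-level heterogeneity at an amplicon locus, under processive
(run-based) methylation kinetics:

```r
amp <- simulate_amplicon_reads(sim_config(seed = 7, amplicon_model = "processive"),
                               20000)
pats <- extract_patterns(amp$reads, amp$cpg_positions)
count_epialleles(pats)
#> <epiallele_summary>
#>   reads: 20000  CpGs: 50
#>   distinct epialleles: 12214
#>   mean per-read methylation: 0.1857

per_read_discordance(pats)
#> [1] 0.8933

head(phase_correlation(pats, bin_width = 50), 4)
#> # A tibble: 4 × 5
#>   bin_start bin_end bin_mid  mean_r n_pairs
#>       <dbl>   <dbl>   <dbl>   <dbl>   <int>
#> 1         0      50      25 0.463       279
#> 2        50     100      75 0.112       243
#> 3       100     150     125 0.0272      207
#> 4       150     200     175 0.00669     171
```

The phase correlation decays with genomic distance — the signature of
processive kinetics; under the distributive model it is flat at zero.

## License

MIT
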