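#' Simulation configuration
#'
#' Bundles all parameters of the synthetic-data generators into a validated
#' configuration object. Defaults describe a two-condition RRBS-style
#' experiment over CpG-island-like regions that start lowly methylated
#' (baseline `Beta(2, 8)`, mean 0.2) and may gain methylation in condition B,
#' a 50-CpG amplicon locus, and a ChIP window-count experiment with a small
#' enriched subpopulation.
#'
#' @param seed Integer seed; the same configuration run twice yields
#'   byte-identical output.
#' @param n_regions Number of regions for [simulate_rrbs_pair()].
#' @param cpgs_per_region CpGs per region.
#' @param coverage_mean Mean per-CpG read coverage (reads).
#' @param coverage_dispersion Negative-binomial size parameter of the coverage
#'   distribution; smaller values give more overdispersed coverage.
#'   Coverage variance is `mu + mu^2/size`.
#' @param baseline_beta_params Length-2 numeric `(alpha, beta)` of the Beta
#'   distribution from which each region's true baseline methylation is drawn.
#' @param dmr_fraction Proportion of regions planted as DMRs, in `[0, 1]`.
#' @param dmr_effect Methylation-fraction shift added to condition B in DMR
#'   regions, in `[0, 1]`; the shifted probability is clipped to `[0, 1]`.
#' @param site_jitter_sd Standard deviation of the per-site, per-condition
#'   Gaussian jitter added to the region methylation before binomial sampling.
#' @param amplicon_model One of `"distributive"`, `"processive"`, `"mixed"`:
#'   independent per-site methylation, run-based methylation, or a per-molecule
#'   mixture of the two.
#' @param site_susceptibility Per-CpG methylation probabilities of the amplicon
#'   locus (one value per CpG, each in `[0, 1]`).
#' @param amplicon_cpg_spacing Genomic spacing between consecutive amplicon
#'   CpGs, in bp.
#' @param processive_run_mean Mean run length of the processive model, in CpGs.
#' @param mixed_weight Probability that a molecule follows the distributive
#'   model under `amplicon_model = "mixed"`.
#' @param chip_lambda_background Poisson mean of background ChIP window counts.
#' @param chip_enrichment_factor Fold enrichment of the enriched subpopulation
#'   (must exceed 1).
#' @param chip_enriched_fraction Proportion of windows that are enriched.
#'
#' @return A list of class `"sim_config"`.
#' @seealso [simulate_rrbs_pair()], [simulate_amplicon_reads()],
#'   [simulate_chip_windows()], [simulate_feature_table()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_regions = 50, dmr_fraction = 0.1, dmr_effect = 0.3)
#' sim <- simulate_rrbs_pair(cfg)
#' head(sim$condition_a)
sim_config <- function(seed = 1L,
                       n_regions = 2000L,
                       cpgs_per_region = 10L,
                       coverage_mean = 30,
                       coverage_dispersion = 15,
                       baseline_beta_params = c(2, 8),
                       dmr_fraction = 0,
                       dmr_effect = 0,
                       site_jitter_sd = 0.05,
                       amplicon_model = c("distributive", "processive", "mixed"),
                       site_susceptibility = rep(0.2, 50),
                       amplicon_cpg_spacing = 8L,
                       processive_run_mean = 5,
                       mixed_weight = 0.5,
                       chip_lambda_background = 10,
                       chip_enrichment_factor = 6,
                       chip_enriched_fraction = 0.05) {
  amplicon_model <- match.arg(amplicon_model)
  cfg <- list(
    seed = as.integer(seed),
    n_regions = as.integer(n_regions),
    cpgs_per_region = as.integer(cpgs_per_region),
    coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    baseline_beta_params = as.numeric(baseline_beta_params),
    dmr_fraction = dmr_fraction,
    dmr_effect = dmr_effect,
    site_jitter_sd = site_jitter_sd,
    amplicon_model = amplicon_model,
    site_susceptibility = as.numeric(site_susceptibility),
    amplicon_cpg_spacing = as.integer(amplicon_cpg_spacing),
    processive_run_mean = processive_run_mean,
    mixed_weight = mixed_weight,
    chip_lambda_background = chip_lambda_background,
    chip_enrichment_factor = chip_enrichment_factor,
    chip_enriched_fraction = chip_enriched_fraction
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid simulation configuration: ", msg, call. = FALSE)
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(cfg$seed) || length(cfg$seed) != 1) stop_cfg("seed must be a single integer")
  if (!num_ok(cfg$n_regions) || cfg$n_regions < 1) stop_cfg("n_regions must be a positive count")
  if (!num_ok(cfg$cpgs_per_region) || cfg$cpgs_per_region < 1) stop_cfg("cpgs_per_region must be a positive count")
  if (!num_ok(cfg$coverage_mean) || cfg$coverage_mean <= 0) stop_cfg("coverage_mean must be positive")
  if (!num_ok(cfg$coverage_dispersion) || cfg$coverage_dispersion <= 0) stop_cfg("coverage_dispersion must be positive")
  if (!num_ok(cfg$baseline_beta_params) || length(cfg$baseline_beta_params) != 2 ||
      any(cfg$baseline_beta_params <= 0)) {
    stop_cfg("baseline_beta_params must be two positive numbers")
  }
  for (nm in c("dmr_fraction", "dmr_effect", "mixed_weight", "chip_enriched_fraction")) {
    v <- cfg[[nm]]
    if (!num_ok(v) || length(v) != 1 || v < 0 || v > 1) stop_cfg(paste(nm, "must be in [0, 1]"))
  }
  if (!num_ok(cfg$site_jitter_sd) || cfg$site_jitter_sd < 0) stop_cfg("site_jitter_sd must be >= 0")
  if (!num_ok(cfg$site_susceptibility) || any(cfg$site_susceptibility < 0) ||
      any(cfg$site_susceptibility > 1)) {
    stop_cfg("site_susceptibility values must be in [0, 1]")
  }
  if (!num_ok(cfg$amplicon_cpg_spacing) || cfg$amplicon_cpg_spacing < 1) stop_cfg("amplicon_cpg_spacing must be >= 1")
  if (!num_ok(cfg$processive_run_mean) || cfg$processive_run_mean < 1) stop_cfg("processive_run_mean must be >= 1 CpG")
  if (!num_ok(cfg$chip_lambda_background) || cfg$chip_lambda_background < 0) stop_cfg("chip_lambda_background must be >= 0")
  if (!num_ok(cfg$chip_enrichment_factor) || cfg$chip_enrichment_factor <= 1) stop_cfg("chip_enrichment_factor must exceed 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  RRBS:", x$n_regions, "regions x", x$cpgs_per_region, "CpGs,",
      "coverage NB(mu =", x$coverage_mean, ", size =", x$coverage_dispersion, ")\n")
  cat("  baseline Beta(", x$baseline_beta_params[1], ",", x$baseline_beta_params[2],
      "), DMR fraction", x$dmr_fraction, "effect", x$dmr_effect, "\n")
  cat("  amplicon:", length(x$site_susceptibility), "CpGs,", x$amplicon_model, "model\n")
  cat("  ChIP: lambda", x$chip_lambda_background, "x", x$chip_enrichment_factor,
      "fold in", x$chip_enriched_fraction, "of windows\n")
  invisible(x)
}
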