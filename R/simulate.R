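#' Simulate a two-condition per-CpG methylation experiment
#'
#' Generates paired per-CpG methylated/unmethylated read counts for two
#' conditions over `n_regions` regions, with a planted subset of regions whose
#' condition-B methylation is shifted by `dmr_effect`. Per region a true
#' methylation fraction is drawn from the configured Beta distribution; each
#' CpG adds independent Gaussian jitter per condition (clipped to `[0, 1]`),
#' coverage is negative-binomial truncated at 1, and methylated counts are
#' binomial. Ground-truth labels are returned alongside, never inside, the
#' count tables.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"rrbs_sim"` with elements `condition_a` and
#'   `condition_b` (tibbles: `chrom`, `start`, `end`, `meth_count`,
#'   `unmeth_count`), `regions` (tibble: `region_id`, `chrom`, `start`, `end`)
#'   and `truth` (tibble: `region_id`, `is_dmr`, `true_meth`), plus the
#'   generating `config`.
#' @export
#' @examples
#' sim <- simulate_rrbs_pair(sim_config(seed = 7, n_regions = 20,
#'                                      dmr_fraction = 0.2, dmr_effect = 0.3))
#' table(sim$truth$is_dmr)
simulate_rrbs_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    n <- config$n_regions
    k <- config$cpgs_per_region
    n_dmr <- round(config$dmr_fraction * n)
    is_dmr <- rep(FALSE, n)
    if (n_dmr > 0) is_dmr[sample.int(n, n_dmr)] <- TRUE
    m <- stats::rbeta(n, config$baseline_beta_params[1], config$baseline_beta_params[2])

    region_id <- sprintf("region_%05d", seq_len(n))
    region_start <- (seq_len(n) - 1L) * 1000L
    # CpGs laid out every 10 bp from the region start
    pos <- rep(region_start, each = k) + (seq_len(k) - 1L) * 10L
    m_site <- rep(m, each = k)
    eff <- rep(ifelse(is_dmr, config$dmr_effect, 0), each = k)

    draw_condition <- function(p_true) {
      p <- pmin(pmax(p_true + stats::rnorm(n * k, 0, config$site_jitter_sd), 0), 1)
      cov <- pmax(1L, stats::rnbinom(n * k, mu = config$coverage_mean,
                                     size = config$coverage_dispersion))
      meth <- stats::rbinom(n * k, cov, p)
      tibble::tibble(chrom = "chrSim", start = pos, end = pos + 1L,
                     meth_count = meth, unmeth_count = cov - meth)
    }
    cond_a <- draw_condition(m_site)
    cond_b <- draw_condition(m_site + eff)

    structure(list(
      condition_a = cond_a,
      condition_b = cond_b,
      regions = tibble::tibble(region_id = region_id, chrom = "chrSim",
                               start = region_start, end = region_start + (k - 1L) * 10L + 1L),
      truth = tibble::tibble(region_id = region_id, is_dmr = is_dmr, true_meth = m),
      config = config
    ), class = "rrbs_sim")
  })
}

#' Simulate per-molecule amplicon methylation patterns
#'
#' Generates read-level methylation patterns (one string over `M`/`U` per
#' sequenced molecule) at an amplicon locus, under one of three accrual
#' models:
#'
#' * `distributive` — every CpG on every molecule is methylated independently
#'   with its own site susceptibility;
#' * `processive` — each molecule receives a Poisson number of processive
#'   "runs": a run starts at a uniformly chosen CpG and methylates a
#'   geometric number (mean `processive_run_mean`) of consecutive CpGs,
#'   truncated at the amplicon edge. The run-initiation rate is calibrated so
#'   the molecule-averaged methylation matches the mean site susceptibility;
#'   per-site profiles are not individually controlled in this mode.
#' * `mixed` — each molecule is distributive with probability `mixed_weight`,
#'   processive otherwise.
#'
#' @param config A [sim_config()] object; `site_susceptibility` defines the
#'   number of CpGs and their marginal methylation probabilities.
#' @param n_reads Number of molecules to draw (positive).
#' @return A list of class `"amplicon_sim"`: `reads` (tibble `read_id`,
#'   `pattern`), `cpg_positions` (bp offsets of the CpGs), and `truth`
#'   (list: `per_site_probability`, `model`).
#' @export
simulate_amplicon_reads <- function(config, n_reads) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (!is.numeric(n_reads) || length(n_reads) != 1 || !is.finite(n_reads) || n_reads <= 0) {
    stop("n_reads must be a positive count", call. = FALSE)
  }
  n_reads <- as.integer(n_reads)
  p <- config$site_susceptibility
  m <- length(p)
  positions <- (seq_len(m) - 1L) * config$amplicon_cpg_spacing

  withr::with_seed(config$seed, {
    model_of <- switch(config$amplicon_model,
      distributive = rep("distributive", n_reads),
      processive   = rep("processive", n_reads),
      mixed        = ifelse(stats::runif(n_reads) < config$mixed_weight,
                            "distributive", "processive")
    )
    meth <- matrix(FALSE, n_reads, m)
    idx_d <- which(model_of == "distributive")
    if (length(idx_d) > 0) {
      meth[idx_d, ] <- matrix(
        stats::runif(length(idx_d) * m) < rep(p, each = length(idx_d)),
        length(idx_d), m
      )
    }
    idx_p <- which(model_of == "processive")
    if (length(idx_p) > 0) {
      pbar <- mean(p)
      # run-initiation rate giving P(site unmethylated) = 1 - pbar for
      # interior sites under the shot-noise approximation
      mu_runs <- if (pbar >= 1) Inf else -log(1 - pbar) * m / config$processive_run_mean
      if (!is.finite(mu_runs)) {
        meth[idx_p, ] <- TRUE
      } else {
        n_runs <- stats::rpois(length(idx_p), mu_runs)
        for (r in seq_along(idx_p)) {
          nr <- n_runs[r]
          if (nr == 0L) next
          starts <- sample.int(m, nr, replace = TRUE)
          lens <- stats::rgeom(nr, prob = 1 / config$processive_run_mean) + 1L
          row <- logical(m)
          for (j in seq_len(nr)) {
            row[starts[j]:min(starts[j] + lens[j] - 1L, m)] <- TRUE
          }
          meth[idx_p[r], ] <- row
        }
      }
    }
    chars <- ifelse(meth, "M", "U")
    patterns <- do.call(paste0, lapply(seq_len(m), function(j) chars[, j]))
    structure(list(
      reads = tibble::tibble(read_id = sprintf("read_%06d", seq_len(n_reads)),
                             pattern = patterns),
      cpg_positions = positions,
      truth = list(per_site_probability = p, model = config$amplicon_model),
      config = config
    ), class = "amplicon_sim")
  })
}

#' Simulate ChIP window read counts with an enriched subpopulation
#'
#' Background windows draw counts from `Poisson(lambda_background)`; an
#' `chip_enriched_fraction` subset draws from
#' `Poisson(lambda_background * chip_enrichment_factor)`.
#'
#' @param config A [sim_config()] object.
#' @param n_windows Number of windows (0 allowed, giving empty output).
#' @return A list of class `"chip_sim"`: `windows` (tibble `window_id`,
#'   `count`) and `truth` (tibble `window_id`, `is_enriched`).
#' @export
simulate_chip_windows <- function(config, n_windows) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (!is.numeric(n_windows) || length(n_windows) != 1 || n_windows < 0) {
    stop("n_windows must be a non-negative count", call. = FALSE)
  }
  n_windows <- as.integer(n_windows)
  withr::with_seed(config$seed, {
    enriched <- stats::runif(n_windows) < config$chip_enriched_fraction
    lambda <- ifelse(enriched,
                     config$chip_lambda_background * config$chip_enrichment_factor,
                     config$chip_lambda_background)
    counts <- stats::rpois(n_windows, lambda)
    structure(list(
      windows = tibble::tibble(window_id = sprintf("win_%06d", seq_len(n_windows)),
                               count = counts),
      truth = tibble::tibble(window_id = sprintf("win_%06d", seq_len(n_windows)),
                             is_enriched = enriched),
      config = config
    ), class = "chip_sim")
  })
}

#' Simulate a CGI feature table with realistic correlation structure
#'
#' Emulates the joint structure of chromatin and sequence features over
#' CpG islands: a latent "openness" variable drives H3K4me3 and DNase
#' positively and H3K27me3 and control methylation negatively, so that
#' H3K4me3 and DNase are mutually correlated and anti-correlated with
#' H3K27me3/control methylation. CpG density, normalized CpG density, GC
#' fraction and H3K36me3 depend only weakly on the latent variable. The
#' hypermethylation label is Bernoulli with logistic probability in the
#' (standardized) features; by default closed, Polycomb-marked islands (low
#' H3K4me3, low DNase, low control methylation, high H3K27me3) are the
#' susceptible class.
#'
#' @param config A [sim_config()] object (used for the seed).
#' @param n_cgis Number of CGIs (positive).
#' @param weights Named numeric vector of logistic weights on the standardized
#'   features; names must be a subset of the eight feature columns. The
#'   default encodes the susceptibility structure described above.
#' @param openness_loading Loading of the latent openness variable on
#'   H3K4me3, DNase (positive) and H3K27me3, control methylation (negative),
#'   in `[0, 1)`. Set to 0 for mutually independent features.
#' @param prevalence Target marginal label prevalence.
#' @return A tibble with `cgi_id`, the eight feature columns (`h3k4me3`,
#'   `h3k27me3`, `h3k36me3`, `dnase`, `cpg_density`,
#'   `normalized_cpg_density`, `gc_fraction`, `control_methylation`) and the
#'   logical `label`; the generating probability is stored in attribute
#'   `"label_probability"`.
#' @export
simulate_feature_table <- function(config, n_cgis,
                                   weights = c(h3k4me3 = -1, dnase = -1,
                                               h3k27me3 = 1, control_methylation = -1),
                                   openness_loading = 0.7,
                                   prevalence = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (!is.numeric(n_cgis) || length(n_cgis) != 1 || n_cgis <= 0) {
    stop("n_cgis must be a positive count", call. = FALSE)
  }
  if (openness_loading < 0 || openness_loading >= 1) {
    stop("openness_loading must be in [0, 1)", call. = FALSE)
  }
  feat_names <- c("h3k4me3", "h3k27me3", "h3k36me3", "dnase", "cpg_density",
                  "normalized_cpg_density", "gc_fraction", "control_methylation")
  if (length(weights) > 0 && (is.null(names(weights)) || !all(names(weights) %in% feat_names))) {
    stop("weights must be named after feature columns", call. = FALSE)
  }
  n_cgis <- as.integer(n_cgis)
  a <- openness_loading
  b <- sqrt(1 - a^2)
  withr::with_seed(config$seed, {
    z <- stats::rnorm(n_cgis) # latent openness
    noise <- function() stats::rnorm(n_cgis)
    tbl <- tibble::tibble(
      cgi_id = sprintf("cgi_%05d", seq_len(n_cgis)),
      h3k4me3 = a * z + b * noise(),
      h3k27me3 = -a * z + b * noise(),
      h3k36me3 = 0.2 * z + sqrt(1 - 0.2^2) * noise(),
      dnase = a * z + b * noise(),
      cpg_density = pmax(0.02, 0.08 + 0.01 * (0.2 * z + noise())),
      normalized_cpg_density = pmax(0.6, 0.75 + 0.08 * (0.2 * z + noise())),
      gc_fraction = pmin(0.75, pmax(0.5, 0.58 + 0.03 * (0.2 * z + noise()))),
      control_methylation = 0.2 * stats::plogis(-1.2 * z + noise())
    )
    std <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
    lp <- rep(0, n_cgis)
    for (nm in names(weights)) lp <- lp + weights[[nm]] * std(tbl[[nm]])
    lp <- lp - mean(lp)
    # calibrate the intercept so the mean generating probability hits the
    # target prevalence (a plain qlogis shift over-shoots for spread-out lp)
    icpt <- stats::uniroot(function(c) mean(stats::plogis(lp + c)) - prevalence,
                           interval = c(-20, 20), tol = 1e-10)$root
    prob <- stats::plogis(lp + icpt)
    tbl$label <- stats::runif(n_cgis) < prob
    attr(tbl, "label_probability") <- prob
    tbl
  })
}
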