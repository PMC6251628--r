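#' Coverage-weighted Welch t-test
#'
#' Two-sample t-test of per-CpG methylation fractions weighted by read
#' coverage, using the effective-sample-size formulation. Per group with
#' values `x_i` and weights `w_i`:
#' mean `m = sum(w x) / sum(w)`, effective sample size
#' `n_eff = sum(w)^2 / sum(w^2)`, and unbiased weighted variance
#' `s^2 = (sum(w (x - m)^2) / sum(w)) * n_eff / (n_eff - 1)`. The statistic
#' is the Welch t on (`m`, `s^2`, `n_eff`) with Welch–Satterthwaite degrees
#' of freedom. With all-equal weights this reduces exactly to the standard
#' unweighted Welch test.
#'
#' @param x_a,w_a Values and positive weights of condition A (>= 2 CpGs).
#' @param x_b,w_b Values and weights of condition B.
#' @param weighted If `FALSE`, ignore the weights (plain Welch fallback for
#'   sensitivity analysis).
#' @return A one-row tibble: `mean_a`, `mean_b`, `diff` (`mean_b - mean_a`),
#'   `t_stat`, `df`, `p_value`, `status` (`"ok"` or `"degenerate"` when both
#'   variances are zero with unequal means, where `p_value` is reported as 0).
#' @export
#' @examples
#' weighted_t_test(c(.1, .2, .3), c(10, 20, 10), c(.5, .6, .7), c(10, 10, 30))
weighted_t_test <- function(x_a, w_a, x_b, w_b, weighted = TRUE) {
  if (length(x_a) < 2 || length(x_b) < 2) {
    stop("each condition needs at least 2 CpGs", call. = FALSE)
  }
  if (length(x_a) != length(w_a) || length(x_b) != length(w_b)) {
    stop("values and weights differ in length", call. = FALSE)
  }
  if (any(c(w_a, w_b) <= 0)) stop("weights must be positive", call. = FALSE)
  if (!weighted) {
    w_a <- rep(1, length(x_a))
    w_b <- rep(1, length(x_b))
  }
  g <- function(x, w) {
    m <- sum(w * x) / sum(w)
    n_eff <- sum(w)^2 / sum(w^2)
    if (n_eff <= 1) return(list(m = m, n_eff = n_eff, s2 = NA_real_))
    s2 <- (sum(w * (x - m)^2) / sum(w)) * n_eff / (n_eff - 1)
    list(m = m, n_eff = n_eff, s2 = s2)
  }
  a <- g(x_a, w_a)
  b <- g(x_b, w_b)
  if (!is.finite(a$s2) || !is.finite(b$s2)) {
    stop("effective sample size <= 1; weights too concentrated", call. = FALSE)
  }
  se2 <- a$s2 / a$n_eff + b$s2 / b$n_eff
  d <- b$m - a$m
  if (se2 == 0) {
    if (d == 0) {
      return(tibble::tibble(mean_a = a$m, mean_b = b$m, diff = 0, t_stat = 0,
                            df = NA_real_, p_value = 1, status = "ok"))
    }
    return(tibble::tibble(mean_a = a$m, mean_b = b$m, diff = d,
                          t_stat = sign(d) * Inf, df = NA_real_, p_value = 0,
                          status = "degenerate"))
  }
  t_stat <- (a$m - b$m) / sqrt(se2)
  df <- se2^2 / ((a$s2 / a$n_eff)^2 / (a$n_eff - 1) + (b$s2 / b$n_eff)^2 / (b$n_eff - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  tibble::tibble(mean_a = a$m, mean_b = b$m, diff = d, t_stat = t_stat,
                 df = df, p_value = p, status = "ok")
}

#' Storey q-values
#'
#' Positive-FDR q-values with the null proportion `pi0` estimated by the
#' lambda smoother over `lambda = 0.05, 0.10, ..., 0.95` (natural cubic
#' smoothing spline, evaluated at the largest lambda), falling back to
#' `pi0 = 1` — i.e. Benjamini–Hochberg — when estimation is unstable (fewer
#' than 100 p-values, or an estimate outside `(0, 1]`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param pi0_method `"smoother"` (default) or `"bh"` to force `pi0 = 1`.
#' @return Numeric vector of q-values, same order as `p`, with the estimated
#'   null proportion attached as attribute `"pi0"`.
#' @export
storey_q_values <- function(p, pi0_method = c("smoother", "bh")) {
  pi0_method <- match.arg(pi0_method)
  if (length(p) == 0) return(numeric())
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  pi0 <- 1
  if (pi0_method == "smoother" && m >= 100) {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    est <- stats::predict(fit, x = max(lambda))$y
    if (is.finite(est) && est > 0 && est <= 1) pi0 <- est
  }
  o <- order(p)
  q_sorted <- pi0 * p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  attr(q, "pi0") <- pi0
  q
}

#' Call differentially methylated regions
#'
#' Per region, gathers the CpGs with coverage of at least `min_cov` in each
#' condition, runs the coverage-weighted Welch t-test, adjusts the p-values
#' of testable regions with [storey_q_values()], and flags DMRs at the given
#' q-value and methylation-difference thresholds. Regions with fewer than
#' `min_cpgs` qualifying CpGs in either condition are reported with status
#' `"insufficient_data"` and excluded from the multiple-testing family.
#'
#' @param cpgs_a,cpgs_b CpG call tibbles ([as_cpg_calls()]) for the two
#'   conditions.
#' @param regions Tibble of regions (`chrom`, `start`, `end`, optional
#'   `region_id`).
#' @param min_cov,min_cpgs Minimum-data rule.
#' @param q_thresh,diff_thresh DMR thresholds (q-value, methylation
#'   difference `mean_b - mean_a`).
#' @param direction `"two_sided"` (|diff| >= threshold) or `"gain"`
#'   (diff >= threshold, for gain-of-methylation designs).
#' @param weighted Passed to [weighted_t_test()].
#' @return A tibble of class `"dmr_result"`, one row per region: coordinates,
#'   `n_cpgs_a`, `n_cpgs_b`, `mean_a`, `mean_b`, `diff`, `t_stat`, `df`,
#'   `p_value`, `q_value`, `status`, `is_dmr`.
#' @export
call_dmrs <- function(cpgs_a, cpgs_b, regions, min_cov = 5L, min_cpgs = 2L,
                      q_thresh = 0.05, diff_thresh = 0.2,
                      direction = c("two_sided", "gain"), weighted = TRUE) {
  direction <- match.arg(direction)
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- sprintf("region_%05d", seq_len(nrow(regions)))
  }
  index <- function(cpgs) {
    cpgs <- ensure_cpg_calls(cpgs)
    qual <- cpgs[cpgs$coverage >= min_cov, , drop = FALSE]
    split(qual[order(qual$start), , drop = FALSE], qual$chrom[order(qual$start)])
  }
  ia <- index(cpgs_a)
  ib <- index(cpgs_b)
  grab <- function(idx, chrom, start, end) {
    cc <- idx[[chrom]]
    if (is.null(cc)) return(NULL)
    lo <- findInterval(start - 0.5, cc$start) + 1L
    hi <- findInterval(end - 0.5, cc$start)
    if (hi < lo) return(NULL)
    cc[lo:hi, c("methylation", "coverage")]
  }
  rows <- purrr::pmap(
    regions[, c("region_id", "chrom", "start", "end")],
    function(region_id, chrom, start, end) {
      a <- grab(ia, chrom, start, end)
      b <- grab(ib, chrom, start, end)
      na <- if (is.null(a)) 0L else nrow(a)
      nb <- if (is.null(b)) 0L else nrow(b)
      base <- tibble::tibble(region_id = region_id, chrom = chrom,
                             start = start, end = end,
                             n_cpgs_a = na, n_cpgs_b = nb)
      if (na < min_cpgs || nb < min_cpgs) {
        return(dplyr::mutate(base, mean_a = NA_real_, mean_b = NA_real_,
                             diff = NA_real_, t_stat = NA_real_, df = NA_real_,
                             p_value = NA_real_, status = "insufficient_data"))
      }
      tt <- weighted_t_test(a$methylation, a$coverage,
                            b$methylation, b$coverage, weighted = weighted)
      dplyr::bind_cols(base, tt)
    })
  out <- dplyr::bind_rows(rows)
  testable <- !is.na(out$p_value)
  if (!any(testable)) {
    warning("no testable regions")
    out$q_value <- NA_real_
    out$is_dmr <- FALSE
  } else {
    out$q_value <- NA_real_
    out$q_value[testable] <- storey_q_values(out$p_value[testable])
    passes_diff <- if (direction == "two_sided") abs(out$diff) >= diff_thresh else out$diff >= diff_thresh
    out$is_dmr <- testable & !is.na(out$q_value) & out$q_value < q_thresh & passes_diff
    out$is_dmr[is.na(out$is_dmr)] <- FALSE
  }
  structure(out, class = c("dmr_result", class(out)),
            q_thresh = q_thresh, diff_thresh = diff_thresh, direction = direction)
}

#' @export
glance.dmr_result <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x),
    n_testable = sum(!is.na(x$p_value)),
    n_dmr = sum(x$is_dmr),
    q_thresh = attr(x, "q_thresh"),
    diff_thresh = attr(x, "diff_thresh"),
    direction = attr(x, "direction")
  )
}

#' @export
tidy.dmr_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Hypergeometric overlap significance
#'
#' Upper-tail probability `P(X >= overlap)` that two sets of the given sizes
#' drawn from a common universe share at least the observed number of
#' elements, with `X` hypergeometric.
#'
#' @param universe Universe size.
#' @param set_a,set_b Sizes of the two sets.
#' @param overlap Observed overlap.
#' @return The p-value.
#' @export
#' @examples
#' hypergeometric_overlap(10, 5, 5, 5) # 1 / choose(10, 5)
hypergeometric_overlap <- function(universe, set_a, set_b, overlap) {
  vals <- c(universe, set_a, set_b, overlap)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (set_a > universe || set_b > universe) stop("set sizes exceed the universe", call. = FALSE)
  if (overlap > min(set_a, set_b)) stop("overlap exceeds the smaller set", call. = FALSE)
  stats::phyper(overlap - 1, set_a, universe - set_a, set_b, lower.tail = FALSE)
}

#' Stratify differentially methylated promoters by expression
#'
#' Bins genes by expression (quantile bins by default, or fixed edges) and
#' counts, per bin, how many carry a differentially methylated promoter.
#'
#' @param dmr_promoters Tibble with `gene_id` and logical `is_dmr` (one row
#'   per tested promoter); an optional `cpg_class` column adds an HCP/LCP
#'   split.
#' @param expression Tibble with `gene_id` and `expression`.
#' @param bins Number of quantile bins, or a numeric vector of fixed bin
#'   edges (length > 1).
#' @return A tibble per (class x) bin: `bin`, `n_genes`, `n_dmr`,
#'   `frac_dmr`.
#' @export
stratify_by_expression <- function(dmr_promoters, expression, bins = 5) {
  stopifnot(all(c("gene_id", "is_dmr") %in% names(dmr_promoters)))
  stopifnot(all(c("gene_id", "expression") %in% names(expression)))
  df <- dplyr::left_join(dmr_promoters, expression, by = "gene_id")
  missing <- is.na(df$expression)
  if (any(missing)) {
    warning(sum(missing), " gene(s) without expression excluded")
    df <- df[!missing, , drop = FALSE]
  }
  if (nrow(df) == 0) return(tibble::tibble(bin = factor(), n_genes = integer(),
                                           n_dmr = integer(), frac_dmr = numeric()))
  if (length(bins) == 1) {
    edges <- unique(stats::quantile(df$expression, probs = seq(0, 1, length.out = bins + 1)))
  } else {
    edges <- bins
  }
  df$bin <- cut(df$expression, breaks = edges, include.lowest = TRUE)
  grouping <- if ("cpg_class" %in% names(df)) c("cpg_class", "bin") else "bin"
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping)), .drop = FALSE) |>
    dplyr::summarise(n_genes = dplyr::n(), n_dmr = sum(.data$is_dmr),
                     frac_dmr = ifelse(dplyr::n() > 0, sum(.data$is_dmr) / dplyr::n(), NA_real_),
                     .groups = "drop")
}
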