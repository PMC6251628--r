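#' Extract per-molecule methylation patterns at an amplicon locus
#'
#' Parses read-level methylation strings over the alphabet `M`
#' (methylated), `U` (unmethylated) and `.` (CpG not covered by the read)
#' into a pattern table. With `require_complete` (the default), reads missing
#' any CpG are dropped and counted — the deep-amplicon design covers every
#' CpG, and partial patterns would conflate coverage with diversity. Reads
#' covering no CpG at all are always rejected and counted separately.
#'
#' @param reads Tibble with `read_id` and `pattern` columns (e.g. from
#'   [simulate_amplicon_reads()] or [read_pattern_table()]).
#' @param cpg_positions Optional bp offsets of the locus CpGs; when given,
#'   pattern length must match its length.
#' @param require_complete Drop reads with missing states.
#' @return A tibble of class `"read_patterns"` (`read_id`, `pattern`,
#'   `n_meth`, `n_covered`) with attributes `cpg_positions`,
#'   `n_dropped_incomplete` and `n_rejected_empty`.
#' @export
extract_patterns <- function(reads, cpg_positions = NULL, require_complete = TRUE) {
  stopifnot(all(c("read_id", "pattern") %in% names(reads)))
  pat <- toupper(reads$pattern)
  if (any(grepl("[^MU.]", pat))) {
    stop("patterns may only contain M, U and . (missing)", call. = FALSE)
  }
  lens <- nchar(pat)
  m <- if (!is.null(cpg_positions)) length(cpg_positions) else max(lens, 0)
  if (any(lens != m)) {
    stop("all patterns must cover the locus's ", m, " CpGs (pad missing CpGs with .)",
         call. = FALSE)
  }
  n_meth <- stringr::str_count(pat, stringr::fixed("M"))
  n_covered <- m - stringr::str_count(pat, stringr::fixed("."))
  empty <- n_covered == 0
  n_rejected <- sum(empty)
  keep <- !empty
  n_dropped <- 0L
  if (require_complete) {
    incomplete <- keep & n_covered < m
    n_dropped <- sum(incomplete)
    keep <- keep & !incomplete
  }
  out <- tibble::tibble(read_id = reads$read_id[keep], pattern = pat[keep],
                        n_meth = n_meth[keep], n_covered = n_covered[keep])
  structure(out, class = c("read_patterns", class(out)),
            cpg_positions = cpg_positions %||% (seq_len(m) - 1L),
            n_dropped_incomplete = n_dropped,
            n_rejected_empty = n_rejected)
}

#' Read a read-pattern TSV
#'
#' Expects columns `read_id` and `pattern` (header line present).
#'
#' @param path Path to the TSV.
#' @return A tibble `read_id`, `pattern`.
#' @export
read_pattern_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    read_id = readr::col_character(), pattern = readr::col_character()
  ), progress = FALSE)
}

#' Epiallele diversity summary
#'
#' Counts distinct complete methylation patterns (epialleles) overall and
#' stratified by the number of methylated CpGs per molecule, and summarises
#' per-read and per-site methylation.
#'
#' @param patterns A `"read_patterns"` tibble with complete reads only (see
#'   [extract_patterns()]).
#' @return A list of class `"epiallele_summary"`:
#'   `total_epialleles`; `per_k` (tibble `k`, `n_epialleles`, `n_reads`);
#'   `per_read_meth` (tibble `n_meth`, `n_reads`, `frac_reads`);
#'   `per_site_meth` (tibble `site`, `position`, `frac_meth`); `n_reads`;
#'   `n_cpgs`.
#' @export
count_epialleles <- function(patterns) {
  if (nrow(patterns) == 0) {
    return(structure(list(total_epialleles = 0L,
                          per_k = tibble::tibble(k = integer(), n_epialleles = integer(),
                                                 n_reads = integer()),
                          per_read_meth = tibble::tibble(n_meth = integer(),
                                                         n_reads = integer(),
                                                         frac_reads = numeric()),
                          per_site_meth = tibble::tibble(site = integer(),
                                                         position = numeric(),
                                                         frac_meth = numeric()),
                          n_reads = 0L, n_cpgs = NA_integer_),
                     class = "epiallele_summary"))
  }
  if (any(patterns$n_covered < nchar(patterns$pattern))) {
    stop("count_epialleles requires complete patterns (no missing states)",
         call. = FALSE)
  }
  m <- nchar(patterns$pattern[1])
  per_k <- patterns |>
    dplyr::group_by(k = .data$n_meth) |>
    dplyr::summarise(n_epialleles = dplyr::n_distinct(.data$pattern),
                     n_reads = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$k)
  per_read <- patterns |>
    dplyr::count(.data$n_meth, name = "n_reads") |>
    dplyr::mutate(frac_reads = .data$n_reads / sum(.data$n_reads))
  chars <- matrix(unlist(strsplit(patterns$pattern, "", fixed = TRUE)),
                  nrow = nrow(patterns), byrow = TRUE)
  pos <- attr(patterns, "cpg_positions") %||% (seq_len(m) - 1L)
  per_site <- tibble::tibble(site = seq_len(m), position = as.numeric(pos),
                             frac_meth = colMeans(chars == "M"))
  structure(list(total_epialleles = dplyr::n_distinct(patterns$pattern),
                 per_k = per_k, per_read_meth = per_read,
                 per_site_meth = per_site,
                 n_reads = nrow(patterns), n_cpgs = m),
            class = "epiallele_summary")
}

#' @export
print.epiallele_summary <- function(x, ...) {
  cat("<epiallele_summary>\n")
  cat("  reads:", x$n_reads, " CpGs:", x$n_cpgs, "\n")
  cat("  distinct epialleles:", x$total_epialleles, "\n")
  if (x$n_reads > 0) {
    cat("  mean per-read methylation:",
        round(sum(x$per_read_meth$n_meth * x$per_read_meth$n_reads) /
                (x$n_reads * x$n_cpgs), 4), "\n")
  }
  invisible(x)
}

#' @export
tidy.epiallele_summary <- function(x, ...) {
  x$per_k
}

#' @export
glance.epiallele_summary <- function(x, ...) {
  mean_meth <- if (x$n_reads > 0) {
    sum(x$per_read_meth$n_meth * x$per_read_meth$n_reads) / (x$n_reads * x$n_cpgs)
  } else NA_real_
  tibble::tibble(total_epialleles = x$total_epialleles, n_reads = x$n_reads,
                 n_cpgs = x$n_cpgs, mean_methylation = mean_meth)
}

#' Proportion of discordantly methylated reads
#'
#' A read is concordant when all its covered CpGs share one state (all
#' methylated or all unmethylated) and discordant otherwise; the statistic is
#' the discordant fraction among reads covering at least `min_covered` CpGs.
#'
#' @param patterns A `"read_patterns"` tibble.
#' @param min_covered Minimum covered CpGs for a read to be eligible.
#' @return Single numeric proportion; `NA` with a warning when no read is
#'   eligible.
#' @export
per_read_discordance <- function(patterns, min_covered = 4L) {
  eligible <- patterns$n_covered >= min_covered
  if (!any(eligible)) {
    warning("no reads with >= ", min_covered, " covered CpGs; discordance undefined")
    return(NA_real_)
  }
  p <- patterns[eligible, , drop = FALSE]
  concordant <- p$n_meth == 0L | p$n_meth == p$n_covered
  mean(!concordant)
}

#' Pairwise in-phase CpG correlation vs genomic distance
#'
#' For every CpG pair, the Pearson correlation (phi coefficient) of their
#' binary methylation states across the reads covering both sites; pairs
#' involving a zero-variance site are excluded and counted. Pair correlations
#' are averaged within genomic-distance bins.
#'
#' @param patterns A `"read_patterns"` tibble.
#' @param cpg_positions bp offsets of the CpGs; defaults to the positions
#'   attached by [extract_patterns()].
#' @param bin_width Distance bin width in bp.
#' @return A tibble (`bin_start`, `bin_end`, `bin_mid`, `mean_r`, `n_pairs`)
#'   with attribute `n_excluded_pairs`; zero rows (with a warning) when no
#'   pair has variance.
#' @export
phase_correlation <- function(patterns, cpg_positions = NULL, bin_width = 25) {
  pos <- cpg_positions %||% attr(patterns, "cpg_positions")
  if (is.null(pos)) stop("cpg_positions required", call. = FALSE)
  if (nrow(patterns) < 2) stop("at least 2 reads required", call. = FALSE)
  m <- length(pos)
  chars <- matrix(unlist(strsplit(patterns$pattern, "", fixed = TRUE)),
                  nrow = nrow(patterns), byrow = TRUE)
  X <- matrix(NA_real_, nrow(chars), m)
  X[chars == "M"] <- 1
  X[chars == "U"] <- 0
  C <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  d <- abs(outer(pos, pos, "-"))
  ut <- upper.tri(d)
  r <- C[ut]
  dist <- d[ut]
  valid <- is.finite(r)
  n_excluded <- sum(!valid)
  if (!any(valid)) {
    warning("no CpG pair with variance at both sites")
    out <- tibble::tibble(bin_start = numeric(), bin_end = numeric(),
                          bin_mid = numeric(), mean_r = numeric(), n_pairs = integer())
    attr(out, "n_excluded_pairs") <- n_excluded
    return(out)
  }
  r <- r[valid]
  dist <- dist[valid]
  bin <- (dist %/% bin_width)
  out <- tibble::tibble(bin = bin, r = r) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_r = mean(.data$r), n_pairs = dplyr::n(), .groups = "drop") |>
    dplyr::transmute(bin_start = .data$bin * bin_width,
                     bin_end = (.data$bin + 1) * bin_width,
                     bin_mid = (.data$bin + 0.5) * bin_width,
                     mean_r = .data$mean_r, n_pairs = .data$n_pairs) |>
    dplyr::arrange(.data$bin_start)
  attr(out, "n_excluded_pairs") <- n_excluded
  out
}
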