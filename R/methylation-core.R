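#' Read a per-CpG coverage table
#'
#' Reads the bedGraph-coverage dialect used throughout the package: a
#' tab-separated file with columns `chrom`, `start`, `end`, `meth_count`,
#' `unmeth_count` and a header line. Rows with zero total coverage are
#' dropped with a warning. Input is assumed to be symmetric-CpG strand-merged
#' (the convention of standard RRBS callers); see [merge_cpg_strands()].
#'
#' @param path Path to the TSV file.
#' @return A tibble `chrom`, `start`, `end`, `meth_count`, `unmeth_count`,
#'   `coverage`, `methylation`.
#' @export
read_cpg_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), meth_count = readr::col_integer(),
    unmeth_count = readr::col_integer()
  ), progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop("malformed CpG table ", path, ": first problem at line ", probs$row[1],
         " (", probs$expected[1], ")", call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("empty CpG table: ", path)
  }
  as_cpg_calls(df)
}

#' Coerce a data frame of per-CpG counts to the package's call format
#'
#' @param df Data frame with `chrom`, `start`, `end` (or `pos`),
#'   `meth_count`, `unmeth_count`.
#' @return A tibble with derived `coverage` and `methylation` columns; rows
#'   with zero coverage are dropped with a warning.
#' @export
as_cpg_calls <- function(df) {
  if (!"start" %in% names(df) && "pos" %in% names(df)) {
    df$start <- df$pos
    df$end <- df$pos + 1L
  }
  stopifnot(all(c("chrom", "start", "meth_count", "unmeth_count") %in% names(df)))
  if (any(df$meth_count < 0 | df$unmeth_count < 0, na.rm = TRUE)) {
    stop("negative counts in CpG table", call. = FALSE)
  }
  cov <- df$meth_count + df$unmeth_count
  if (any(cov == 0)) {
    warning(sum(cov == 0), " CpG row(s) with zero coverage dropped")
    df <- df[cov > 0, , drop = FALSE]
    cov <- cov[cov > 0]
  }
  tibble::as_tibble(df) |>
    dplyr::mutate(coverage = .data$meth_count + .data$unmeth_count,
                  methylation = .data$meth_count / .data$coverage)
}

#' Merge opposite-strand CpG calls
#'
#' Sums the counts of the two C's of a symmetric CpG (plus-strand position
#' `p`, minus-strand position `p + 1`) into one call at the plus-strand
#' position. Requires a `strand` column to identify minus-strand calls. Use
#' only on input that is not already strand-merged.
#'
#' @param cpgs A CpG call tibble (see [as_cpg_calls()]) with a `strand`
#'   column over `{"+", "-"}`.
#' @return A strand-merged CpG call tibble.
#' @export
merge_cpg_strands <- function(cpgs) {
  if (!"strand" %in% names(cpgs)) {
    stop("merge_cpg_strands requires a strand column", call. = FALSE)
  }
  cpgs |>
    dplyr::mutate(anchor = ifelse(.data$strand == "-", .data$start - 1L, .data$start)) |>
    dplyr::group_by(.data$chrom, .data$anchor) |>
    dplyr::summarise(meth_count = sum(.data$meth_count),
                     unmeth_count = sum(.data$unmeth_count), .groups = "drop") |>
    dplyr::transmute(chrom = .data$chrom, start = .data$anchor,
                     end = .data$anchor + 1L,
                     meth_count = .data$meth_count,
                     unmeth_count = .data$unmeth_count) |>
    as_cpg_calls()
}

#' Coverage-weighted median
#'
#' The lower weighted median: after sorting by value, the smallest value
#' whose cumulative weight reaches half of the total weight. For integer
#' weights this equals the lower median of the expansion that repeats each
#' value `weight` times.
#'
#' @param values Numeric vector.
#' @param weights Positive numeric weights, same length.
#' @return A single numeric value.
#' @export
#' @examples
#' weighted_median(c(0, 1), c(30, 10)) # 0: half the 40 expanded values are 0
weighted_median <- function(values, weights) {
  if (length(values) == 0) stop("weighted_median of empty input", call. = FALSE)
  if (length(values) != length(weights)) stop("values and weights differ in length", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o])
  v[which(cw >= cw[length(cw)] / 2)[1]]
}

#' Feature-level methylation
#'
#' Coverage-weighted median methylation per genomic feature, applying the
#' minimum-data rule: a feature is called only when at least `min_cpgs` CpGs
#' inside it have coverage of at least `min_cov` reads; otherwise its status
#' is `"insufficient_data"`.
#'
#' @param cpgs CpG call tibble ([as_cpg_calls()]).
#' @param features Tibble with `chrom`, `start`, `end` and optionally a
#'   `feature_id` column (generated when absent).
#' @param min_cov Minimum per-CpG coverage.
#' @param min_cpgs Minimum qualifying CpGs per feature.
#' @param stat `"median"` (default, coverage-weighted median) or `"mean"`
#'   (coverage-weighted mean).
#' @return A tibble (`feature_id`, `chrom`, `start`, `end`, `n_cpgs_used`,
#'   `total_weight`, `value`, `status`).
#' @export
feature_methylation <- function(cpgs, features, min_cov = 5L, min_cpgs = 2L,
                                stat = c("median", "mean")) {
  stat <- match.arg(stat)
  stopifnot(all(c("chrom", "start", "end") %in% names(features)))
  if (!"feature_id" %in% names(features)) {
    features$feature_id <- sprintf("feature_%05d", seq_len(nrow(features)))
  }
  cpgs <- ensure_cpg_calls(cpgs)
  qual <- cpgs[cpgs$coverage >= min_cov, , drop = FALSE]
  by_chrom <- split(qual[order(qual$start), , drop = FALSE], qual$chrom[order(qual$start)])
  rows <- purrr::pmap(
    features[, c("feature_id", "chrom", "start", "end")],
    function(feature_id, chrom, start, end) {
      cc <- by_chrom[[chrom]]
      if (is.null(cc)) {
        idx <- integer()
      } else {
        lo <- findInterval(start - 0.5, cc$start) + 1L
        hi <- findInterval(end - 0.5, cc$start)
        idx <- if (hi >= lo) lo:hi else integer()
      }
      n <- length(idx)
      if (n < min_cpgs) {
        return(tibble::tibble(feature_id = feature_id, chrom = chrom, start = start,
                              end = end, n_cpgs_used = n,
                              total_weight = if (n) sum(cc$coverage[idx]) else 0,
                              value = NA_real_, status = "insufficient_data"))
      }
      x <- cc$methylation[idx]
      w <- cc$coverage[idx]
      v <- if (stat == "median") weighted_median(x, w) else sum(w * x) / sum(w)
      tibble::tibble(feature_id = feature_id, chrom = chrom, start = start,
                     end = end, n_cpgs_used = n, total_weight = sum(w),
                     value = v, status = "called")
    })
  dplyr::bind_rows(rows)
}

#' Fixed-tile methylation (and paired deltas)
#'
#' Partitions each chromosome into fixed non-overlapping tiles starting at
#' position 0 and computes, per tile, the coverage-weighted mean methylation
#' over CpGs with coverage of at least `min_cov`, requiring at least
#' `min_cpgs` such CpGs. When a second condition is supplied, tiles called in
#' both conditions gain `delta = value_b - value_a`.
#'
#' @param cpgs CpG call tibble for the (control) condition.
#' @param tile_size Tile width in bp.
#' @param min_cov,min_cpgs Minimum-data rule as in [feature_methylation()].
#' @param cpgs_b Optional CpG call tibble for the second condition.
#' @return A tibble of called tiles (`chrom`, `start`, `end`, `n_cpgs_used`,
#'   `value`, and with `cpgs_b`: `value_b`, `delta`).
#' @export
tile_methylation <- function(cpgs, tile_size = 100L, min_cov = 5L, min_cpgs = 2L,
                             cpgs_b = NULL) {
  one <- function(cc) {
    cc <- ensure_cpg_calls(cc)
    cc <- cc[cc$coverage >= min_cov, , drop = FALSE]
    cc$tile <- (cc$start %/% tile_size) * tile_size
    cc |>
      dplyr::group_by(.data$chrom, .data$tile) |>
      dplyr::summarise(n_cpgs_used = dplyr::n(),
                       value = sum(.data$coverage * .data$methylation) / sum(.data$coverage),
                       .groups = "drop") |>
      dplyr::filter(.data$n_cpgs_used >= min_cpgs) |>
      dplyr::transmute(chrom = .data$chrom, start = .data$tile,
                       end = .data$tile + tile_size,
                       n_cpgs_used = .data$n_cpgs_used, value = .data$value)
  }
  a <- one(cpgs)
  if (is.null(cpgs_b)) return(a)
  b <- one(cpgs_b)
  dplyr::inner_join(a, b, by = c("chrom", "start", "end"),
                    suffix = c("", "_b")) |>
    dplyr::mutate(delta = .data$value_b - .data$value)
}

#' Write a CpG call tibble to the package's TSV dialect
#' @param cpgs CpG call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpg_table <- function(cpgs, path) {
  readr::write_tsv(cpgs[, c("chrom", "start", "end", "meth_count", "unmeth_count")], path)
  invisible(path)
}

# add derived coverage/methylation columns when absent
ensure_cpg_calls <- function(cpgs) {
  if (!all(c("coverage", "methylation") %in% names(cpgs))) as_cpg_calls(cpgs) else cpgs
}
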