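#' Count ChIP read starts in fixed windows around anchors
#'
#' Each anchor (a CGI or a TSS) gets a window of `width` bp centred on its
#' midpoint (clipped at chromosome edges when lengths are supplied); a read
#' is counted when its 5' position falls in the half-open window.
#'
#' @param reads Tibble of read 5' positions: `chrom`, `pos`.
#' @param anchors Tibble `chrom`, `start`, `end` (and optional `anchor_id`).
#' @param width Window width in bp (1,000 is typical for H3K4me3, 5,000 for
#'   H3K27me3).
#' @param chrom_lengths Optional named vector used to clip windows.
#' @return A tibble (`anchor_id`, `chrom`, `window_start`, `window_end`,
#'   `window_width`, `count`).
#' @export
count_reads_in_windows <- function(reads, anchors, width, chrom_lengths = NULL) {
  stopifnot(all(c("chrom", "pos") %in% names(reads)))
  stopifnot(all(c("chrom", "start", "end") %in% names(anchors)))
  if (!"anchor_id" %in% names(anchors)) {
    anchors$anchor_id <- sprintf("anchor_%05d", seq_len(nrow(anchors)))
  }
  mid <- (anchors$start + anchors$end) %/% 2L
  ws <- mid - width %/% 2L
  we <- ws + width
  ws <- pmax(0L, ws)
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[anchors$chrom])
    we <- pmin(we, ifelse(is.na(len), we, len))
  }
  pos_by_chrom <- split(reads$pos, reads$chrom)
  pos_by_chrom <- lapply(pos_by_chrom, sort)
  count <- purrr::map_int(seq_len(nrow(anchors)), function(i) {
    p <- pos_by_chrom[[anchors$chrom[i]]]
    if (is.null(p)) return(0L)
    # reads with ws <= pos < we
    as.integer(findInterval(we[i] - 0.5, p) - findInterval(ws[i] - 0.5, p))
  })
  tibble::tibble(anchor_id = anchors$anchor_id, chrom = anchors$chrom,
                 window_start = ws, window_end = we,
                 window_width = we - ws, count = count)
}

#' Reads per kilobase per million mapped reads
#'
#' @param count Read count(s) in the region.
#' @param region_length_bp Region length(s) in bp (> 0).
#' @param total_mapped_reads Library size (> 0).
#' @return Numeric RPKM value(s).
#' @export
#' @examples
#' rpkm(100, 1000, 1e7) # 10
rpkm <- function(count, region_length_bp, total_mapped_reads) {
  if (any(region_length_bp <= 0)) stop("region length must be positive", call. = FALSE)
  if (any(total_mapped_reads <= 0)) stop("total mapped reads must be positive", call. = FALSE)
  count / (region_length_bp / 1000) / (total_mapped_reads / 1e6)
}

#' Poisson enrichment test on window counts
#'
#' Fits a single Poisson to the global distribution of window read counts
#' (lambda = the mean count, optionally a trimmed mean to resist inflation by
#' enriched windows) and computes upper-tail p-values
#' `P(X >= k) = 1 - F(k - 1; lambda)`, Storey q-values, and enrichment flags
#' at `q < q_thresh`.
#'
#' @param counts Integer vector of window counts (>= 2 windows), or a tibble
#'   with a `count` column (e.g. from [count_reads_in_windows()]), whose
#'   columns are carried through.
#' @param q_thresh Enrichment q-value threshold.
#' @param lambda Optional known background mean, overriding estimation.
#' @param trim Trim fraction for a robust lambda estimate (0 = plain mean,
#'   the literal global fit).
#' @param randomize If `TRUE`, p-values are the randomized (U-smoothed)
#'   version `P(X > k) + U * P(X = k)`, exactly uniform under the fitted
#'   null — a calibration diagnostic for this discrete test, not an
#'   inferential mode.
#' @return A tibble with `count`, `lambda`, `p_value`, `q_value`, `enriched`
#'   (plus any input columns).
#' @export
poisson_enrichment <- function(counts, q_thresh = 0.05, lambda = NULL,
                               trim = 0, randomize = FALSE) {
  tbl <- if (is.data.frame(counts)) tibble::as_tibble(counts) else tibble::tibble(count = counts)
  if (!"count" %in% names(tbl)) stop("counts must contain a count column", call. = FALSE)
  k <- tbl$count
  if (length(k) < 2) stop("at least 2 windows required", call. = FALSE)
  if (any(k < 0)) stop("negative counts", call. = FALSE)
  lam <- if (!is.null(lambda)) lambda else mean(k, trim = trim)
  if (randomize) {
    p <- stats::ppois(k, lam, lower.tail = FALSE) +
      stats::runif(length(k)) * stats::dpois(k, lam)
  } else {
    p <- stats::ppois(k - 1, lam, lower.tail = FALSE)
  }
  q <- storey_q_values(p)
  tbl$lambda <- lam
  tbl$p_value <- p
  tbl$q_value <- q
  tbl$enriched <- q < q_thresh
  tbl
}

#' Four-way chromatin-state classification of CGIs
#'
#' Combines the enrichment flags of the H3K4me3 and H3K27me3 tests on a
#' common anchor set into the states `H3K4me3_only`, `H3K27me3_only`,
#' `bivalent` (both) and `neither`.
#'
#' @param k4_windows,k27_windows Tibbles from [poisson_enrichment()] with
#'   `anchor_id` and `enriched`, computed on the same anchors.
#' @return A tibble (`anchor_id`, `k4_enriched`, `k27_enriched`, `state`),
#'   `state` a factor with the four levels above.
#' @export
classify_cgi_states <- function(k4_windows, k27_windows) {
  stopifnot(all(c("anchor_id", "enriched") %in% names(k4_windows)),
            all(c("anchor_id", "enriched") %in% names(k27_windows)))
  if (!setequal(k4_windows$anchor_id, k27_windows$anchor_id) ||
      nrow(k4_windows) != nrow(k27_windows)) {
    stop("the two marks must be computed on the same anchor set", call. = FALSE)
  }
  df <- dplyr::inner_join(
    dplyr::select(k4_windows, "anchor_id", k4_enriched = "enriched"),
    dplyr::select(k27_windows, "anchor_id", k27_enriched = "enriched"),
    by = "anchor_id"
  )
  df$state <- factor(
    dplyr::case_when(
      df$k4_enriched & df$k27_enriched ~ "bivalent",
      df$k4_enriched ~ "H3K4me3_only",
      df$k27_enriched ~ "H3K27me3_only",
      TRUE ~ "neither"
    ),
    levels = c("H3K4me3_only", "H3K27me3_only", "bivalent", "neither")
  )
  df
}

#' Composite signal profile around TSSs
#'
#' Bins read positions (or CpG methylation calls) relative to stranded
#' anchors and averages per bin across anchors, optionally per anchor group.
#' Offsets are oriented by strand: upstream of the TSS is negative.
#'
#' @param signal For read density: tibble `chrom`, `pos`. For methylation:
#'   a CpG call tibble (`chrom`, `start`, `methylation`, `coverage`) with
#'   `mode = "methylation"`.
#' @param anchors Tibble `chrom`, `tss`, optional `strand` (anchors without
#'   strand default to `+` with a warning) and optional `group`.
#' @param flank Half-width of the profiled region in bp.
#' @param bin Bin width in bp.
#' @param mode `"reads"` (mean per-anchor read count per bin, optionally
#'   RPKM-normalized via `total_mapped_reads`) or `"methylation"`
#'   (coverage-weighted mean methylation per bin).
#' @param total_mapped_reads Optional library size for RPKM normalization of
#'   read profiles.
#' @return A tibble (`group`, `bin_start`, `bin_mid`, `value`, `n`); `n` is
#'   the number of anchors (reads mode) or CpG observations (methylation
#'   mode) behind each bin.
#' @export
composite_profile <- function(signal, anchors, flank = 5000L, bin = 100L,
                              mode = c("reads", "methylation"),
                              total_mapped_reads = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("chrom", "tss") %in% names(anchors)))
  if (!"strand" %in% names(anchors)) {
    warning("anchors without strand; assuming +")
    anchors$strand <- "+"
  }
  if (!"group" %in% names(anchors)) anchors$group <- "all"
  pos_col <- if (mode == "reads") "pos" else "start"
  stopifnot(pos_col %in% names(signal))
  n_bins <- 2L * (flank %/% bin)
  bin_starts <- (seq_len(n_bins) - 1L) * bin - flank

  per_anchor <- purrr::pmap(
    anchors[, c("chrom", "tss", "strand", "group")],
    function(chrom, tss, strand, group) {
      sel <- signal$chrom == chrom & signal[[pos_col]] >= tss - flank &
        signal[[pos_col]] < tss + flank
      if (!any(sel)) {
        if (mode == "reads") {
          return(tibble::tibble(group = group, bin_start = bin_starts, count = 0))
        }
        return(NULL)
      }
      off <- signal[[pos_col]][sel] - tss
      if (strand == "-") off <- -off - 1L
      b <- (off %/% bin) * bin
      # oriented offsets stay inside [-flank, flank); guard the reflection edge
      keep <- b >= -flank & b < flank
      b <- b[keep]
      if (mode == "reads") {
        cnt <- table(factor(b, levels = bin_starts))
        return(tibble::tibble(group = group, bin_start = bin_starts,
                              count = as.numeric(cnt)))
      }
      tibble::tibble(group = group, bin_start = b,
                     methylation = signal$methylation[sel][keep],
                     coverage = signal$coverage[sel][keep])
    })
  df <- dplyr::bind_rows(per_anchor)
  if (mode == "reads") {
    out <- df |>
      dplyr::group_by(.data$group, .data$bin_start) |>
      dplyr::summarise(value = mean(.data$count), n = dplyr::n(), .groups = "drop")
    if (!is.null(total_mapped_reads)) {
      out$value <- rpkm(out$value, bin, total_mapped_reads)
    }
  } else {
    if (nrow(df) == 0) {
      return(tibble::tibble(group = character(), bin_start = integer(),
                            bin_mid = numeric(), value = numeric(), n = integer()))
    }
    out <- df |>
      dplyr::group_by(.data$group, .data$bin_start) |>
      dplyr::summarise(value = sum(.data$coverage * .data$methylation) / sum(.data$coverage),
                       n = dplyr::n(), .groups = "drop")
  }
  out$bin_mid <- out$bin_start + bin / 2
  dplyr::relocate(out, "bin_mid", .after = "bin_start")
}
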