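#' CpG statistics of a DNA sequence
#'
#' Computes, per sequence, the GC fraction, the CpG observed/expected ratio
#' and the CpG dinucleotide count. With sequence length `L`, `n_C` C's,
#' `n_G` G's and `n_CpG` "CG" dinucleotides, the ratio is
#' `n_CpG * L / (n_C * n_G)` (0 when either base is absent). Ambiguity codes
#' (N) are permitted and count toward `L` only.
#'
#' @param sequence Character vector of DNA sequences (case-insensitive), or a
#'   [Biostrings::DNAStringSet].
#' @return A tibble with one row per sequence: `length`, `n_cpg`,
#'   `gc_fraction`, `obs_exp_ratio`.
#' @export
#' @examples
#' compute_obs_exp("CGCGCG") # obs/exp = 2, GC = 1
compute_obs_exp <- function(sequence) {
  if (inherits(sequence, "DNAStringSet")) sequence <- as.character(sequence)
  if (!is.character(sequence) || length(sequence) == 0 || any(!nzchar(sequence))) {
    stop("sequence must be one or more non-empty DNA strings", call. = FALSE)
  }
  s <- toupper(sequence)
  L <- nchar(s)
  n_c <- stringr::str_count(s, stringr::fixed("C"))
  n_g <- stringr::str_count(s, stringr::fixed("G"))
  n_cpg <- stringr::str_count(s, stringr::fixed("CG"))
  obs_exp <- ifelse(n_c == 0 | n_g == 0, 0, n_cpg * L / (n_c * n_g))
  tibble::tibble(length = L, n_cpg = n_cpg,
                 gc_fraction = (n_c + n_g) / L,
                 obs_exp_ratio = obs_exp)
}

#' Detect CpG islands by sliding-window scan
#'
#' Finds CpG islands — regions with GC fraction > `min_gc`, length >
#' `min_length` bp and CpG observed/expected ratio > `min_obs_exp` — with a
#' 1-bp-step sliding window of `window` bp. Qualifying windows are merged
#' into maximal spans, each span is trimmed (if needed) until the reported
#' region itself satisfies all three thresholds, and regions not exceeding
#' `min_length` are dropped. Reported boundaries carry an inherent tolerance
#' of about one window width.
#'
#' @param genome Named character vector of chromosome sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @param window Scan window width in bp.
#' @param min_gc,min_length,min_obs_exp The three defining thresholds.
#' @return A tibble (`chrom`, `start`, `end` 0-based half-open, `length`,
#'   `n_cpg`, `gc_fraction`, `obs_exp_ratio`), one row per island.
#' @export
detect_cgis <- function(genome, window = 200L, min_gc = 0.5,
                        min_length = 200L, min_obs_exp = 0.6) {
  genome <- as_genome_chr(genome)
  res <- purrr::imap(genome, function(seq, chrom) {
    spans <- scan_cgi_spans(seq, window, min_gc, min_obs_exp)
    if (nrow(spans) == 0) return(NULL)
    trimmed <- purrr::pmap(spans, function(start, end) {
      trim_island(seq, start, end, min_gc, min_length, min_obs_exp)
    })
    trimmed <- dplyr::bind_rows(trimmed)
    if (nrow(trimmed) == 0) return(NULL)
    dplyr::mutate(trimmed, chrom = chrom, .before = 1)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          length = integer(), n_cpg = integer(),
                          gc_fraction = numeric(), obs_exp_ratio = numeric()))
  }
  out
}

# merged 0-based half-open spans of qualifying fixed-width windows
scan_cgi_spans <- function(seq, window, min_gc, min_obs_exp) {
  L <- nchar(seq)
  empty <- tibble::tibble(start = integer(), end = integer())
  if (L < window + 1) return(empty)
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  isC <- b == "C"
  isG <- b == "G"
  isCG <- isC & c(b[-1] == "G", FALSE)
  cC <- c(0L, cumsum(isC))
  cG <- c(0L, cumsum(isG))
  cCG <- c(0L, cumsum(isCG))
  starts <- seq_len(L - window + 1L) # 1-based window starts
  nC <- cC[starts + window] - cC[starts]
  nG <- cG[starts + window] - cG[starts]
  # CG dinucleotides fully inside the window start at positions s..s+window-2
  nCG <- cCG[starts + window - 1L] - cCG[starts]
  gc_ok <- (nC + nG) / window > min_gc
  oe_ok <- nC > 0 & nG > 0 & (nCG * window) / pmax(nC * nG, 1) > min_obs_exp
  ok <- gc_ok & oe_ok
  if (!any(ok)) return(empty)
  r <- rle(ok)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values)
  span_start <- starts[run_start[keep]] - 1L           # 0-based
  span_end <- starts[run_end[keep]] - 1L + window      # half-open
  # merge spans that overlap (possible when runs are separated by < window)
  o <- order(span_start)
  span_start <- span_start[o]; span_end <- span_end[o]
  ms <- span_start[1]; me <- span_end[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(span_start)[-1]) {
    if (span_start[i] <= me) {
      me <- max(me, span_end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- span_start[i]; me <- span_end[i]
    }
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

# shrink a candidate span until it passes all thresholds itself
trim_island <- function(seq, start, end, min_gc, min_length, min_obs_exp) {
  passes <- function(st) st$gc_fraction > min_gc & st$obs_exp_ratio > min_obs_exp
  while (end - start > min_length) {
    st <- compute_obs_exp(substr(seq, start + 1L, end))
    if (passes(st)) {
      return(tibble::tibble(start = start, end = end, length = end - start,
                            n_cpg = st$n_cpg, gc_fraction = st$gc_fraction,
                            obs_exp_ratio = st$obs_exp_ratio))
    }
    # drop the weaker end: trim the side whose terminal base is not C/G,
    # preferring the left on ties
    left <- toupper(substr(seq, start + 1L, start + 1L))
    right <- toupper(substr(seq, end, end))
    if (!(left %in% c("C", "G"))) start <- start + 1L
    else if (!(right %in% c("C", "G"))) end <- end - 1L
    else start <- start + 1L
  }
  tibble::tibble(start = integer(), end = integer(), length = integer(),
                 n_cpg = integer(), gc_fraction = numeric(), obs_exp_ratio = numeric())
}

as_genome_chr <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (!is.character(genome) || is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome must be a named character vector, DNAStringSet or FASTA path",
         call. = FALSE)
  }
  genome
}

#' Define CpG-island shores
#'
#' Shores are the 2-kb flanks of each island, clipped at chromosome edges and
#' truncated so they never overlap any island.
#'
#' @param cgis Tibble of islands (`chrom`, `start`, `end`), e.g. from
#'   [detect_cgis()].
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param flank Shore width in bp.
#' @return A tibble (`chrom`, `start`, `end`, `side`, `cgi_start`,
#'   `cgi_end`); empty-width shores are dropped.
#' @export
define_shores <- function(cgis, chrom_lengths, flank = 2000L) {
  stopifnot(all(c("chrom", "start", "end") %in% names(cgis)))
  out <- cgis |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      len <- chrom_lengths[[key$chrom]]
      if (is.null(len)) stop("no chromosome length for ", key$chrom, call. = FALSE)
      islands <- df[order(df$start), c("start", "end")]
      cand <- dplyr::bind_rows(
        tibble::tibble(start = pmax(0, df$start - flank), end = df$start,
                       side = "upstream", cgi_start = df$start, cgi_end = df$end),
        tibble::tibble(start = df$end, end = pmin(len, df$end + flank),
                       side = "downstream", cgi_start = df$start, cgi_end = df$end)
      )
      pieces <- purrr::pmap(cand, function(start, end, side, cgi_start, cgi_end) {
        segs <- subtract_intervals(start, end, islands)
        if (nrow(segs) == 0) return(NULL)
        tibble::tibble(start = segs$start, end = segs$end, side = side,
                       cgi_start = cgi_start, cgi_end = cgi_end)
      })
      dplyr::bind_rows(pieces)
    }) |>
    dplyr::ungroup()
  out[out$end > out$start, , drop = FALSE]
}

# [start, end) minus a tibble of sorted disjoint intervals
subtract_intervals <- function(start, end, intervals) {
  s <- start; out_s <- integer(); out_e <- integer()
  hits <- intervals[intervals$end > start & intervals$start < end, , drop = FALSE]
  if (nrow(hits) > 0) {
    for (i in seq_len(nrow(hits))) {
      if (hits$start[i] > s) { out_s <- c(out_s, s); out_e <- c(out_e, hits$start[i]) }
      s <- max(s, hits$end[i])
    }
  }
  if (s < end) { out_s <- c(out_s, s); out_e <- c(out_e, end) }
  tibble::tibble(start = out_s, end = out_e)
}

#' Classify promoters by CpG-island overlap
#'
#' Promoters are TSS +/- `flank` bp (clipped at chromosome edges when lengths
#' are supplied). A promoter overlapping at least 1 bp of any CpG island is a
#' high-CpG-density promoter (HCP); all others are LCP.
#'
#' @param tss Tibble with `chrom`, `tss` (0-based position), `gene_id` and
#'   optionally `strand`; see [read_tss_bed()].
#' @param cgis Island tibble (`chrom`, `start`, `end`).
#' @param chrom_lengths Optional named vector of chromosome lengths; TSS
#'   records outside bounds are dropped with a warning.
#' @param flank Promoter half-width in bp.
#' @return A tibble (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `cpg_class`), `cpg_class` in `{"HCP", "LCP"}`.
#' @export
classify_promoters <- function(tss, cgis, chrom_lengths = NULL, flank = 500L) {
  stopifnot(all(c("chrom", "tss", "gene_id") %in% names(tss)))
  if (!"strand" %in% names(tss)) tss$strand <- "+"
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[tss$chrom])
    bad <- is.na(len) | tss$tss < 0 | tss$tss >= len
    if (any(bad)) {
      warning(sum(bad), " TSS record(s) outside chromosome bounds dropped")
      tss <- tss[!bad, , drop = FALSE]
      len <- len[!bad]
    }
    start <- pmax(0, tss$tss - flank)
    end <- pmin(len, tss$tss + flank)
  } else {
    start <- pmax(0, tss$tss - flank)
    end <- tss$tss + flank
  }
  prom <- tibble::tibble(gene_id = tss$gene_id, chrom = tss$chrom,
                         start = start, end = end, strand = tss$strand)
  is_hcp <- purrr::pmap_lgl(prom, function(gene_id, chrom, start, end, strand) {
    any(cgis$chrom == chrom & cgis$end > start & cgis$start < end)
  })
  prom$cpg_class <- ifelse(is_hcp, "HCP", "LCP")
  prom
}

#' Read a BED6 file of transcription start sites
#'
#' Uses the BED `start` column as the (0-based) TSS position and the `name`
#' column as the gene id.
#'
#' @param path Path to a BED file (3-6 columns, no header).
#' @return A tibble `chrom`, `tss`, `gene_id`, `strand`.
#' @export
read_tss_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = cols[seq_len(max(count_bed_fields(path), 3))],
                          stringsAsFactors = FALSE, fill = TRUE)
  tibble::tibble(
    chrom = as.character(df$chrom),
    tss = as.integer(df$start),
    gene_id = if ("name" %in% names(df)) as.character(df$name) else sprintf("gene_%d", seq_len(nrow(df))),
    strand = if ("strand" %in% names(df)) as.character(df$strand) else "+"
  )
}

count_bed_fields <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) return(3L)
  length(strsplit(first, "\t", fixed = TRUE)[[1]])
}
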