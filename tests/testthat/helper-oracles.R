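# Independent oracles used across the suite. Each deliberately uses a
# different algorithm from the implementation it checks.

# lower median of the expansion repeating each value weight-many times
oracle_weighted_median <- function(values, int_weights) {
  expanded <- sort(rep(values, times = int_weights))
  expanded[ceiling(length(expanded) / 2)]
}

# merged union of every window-length substring passing all three CGI
# thresholds, found by literally extracting and counting each substring
# (no cumulative sums). Note the union over substrings of *unbounded*
# length is provably wider than any fixed-window scan: appending background
# sequence to a dense island dilutes GC towards 0.5 only linearly, so
# marginal kilobase-scale substrings qualify far outside the island.
oracle_cgi_union <- function(seq, window = 200, min_gc = 0.5, min_oe = 0.6) {
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(b)
  covered <- logical(L)
  for (s in seq_len(max(L - window + 1, 0))) {
    w <- b[s:(s + window - 1)]
    nC <- sum(w == "C")
    nG <- sum(w == "G")
    nCG <- sum(w[-window] == "C" & w[-1] == "G")
    if (nC > 0 && nG > 0 && (nC + nG) / window > min_gc &&
        (nCG * window) / (nC * nG) > min_oe) {
      covered[s:(s + window - 1)] <- TRUE
    }
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start = starts[keep] - 1L, end = ends[keep]) # 0-based half-open
}

# brute-force window counting by looping reads
oracle_window_count <- function(read_chrom, read_pos, chrom, ws, we) {
  sum(read_chrom == chrom & read_pos >= ws & read_pos < we)
}

# brute-force precision-recall sweep over the distinct scores
oracle_pr <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(th))
  for (i in seq_along(th)) {
    called <- scores >= th[i]
    prec[i] <- sum(labels & called) / sum(called)
    rec[i] <- sum(labels & called) / sum(labels)
  }
  data.frame(threshold = th, precision = prec, recall = rec)
}

# exhaustive enumeration of overlap tail probability: fix set A, enumerate
# every possible set B of the given size
oracle_hypergeom <- function(universe, a, b, overlap) {
  sets <- utils::combn(universe, b)
  ov <- colSums(sets <= a) # WLOG A = {1..a}
  mean(ov >= overlap)
}

# random DNA with given GC content
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# AT-rich toy chromosome with planted CG-rich segments at known offsets
planted_chromosome <- function(total, segments) {
  chrom <- strsplit(random_dna(total, gc = 0.30), "")[[1]]
  for (seg in segments) {
    piece <- strsplit(paste(rep("CG", ceiling(seg$len / 2)), collapse = ""), "")[[1]]
    piece <- piece[seq_len(seg$len)]
    # dilute the pure repeat with some A/T to keep it island-like but not trivial
    swap <- sample(seg$len, round(seg$len * 0.15))
    piece[swap] <- sample(c("A", "T"), length(swap), replace = TRUE)
    chrom[(seg$at + 1):(seg$at + seg$len)] <- piece
  }
  paste(chrom, collapse = "")
}

sim_truth_recovery <- function(dmr_tbl, truth) {
  m <- merge(as.data.frame(dmr_tbl)[, c("region_id", "is_dmr")],
             as.data.frame(truth)[, c("region_id", "is_dmr")],
             by = "region_id", suffixes = c("_called", "_true"))
  list(
    sensitivity = sum(m$is_dmr_called & m$is_dmr_true) / sum(m$is_dmr_true),
    fdr = if (sum(m$is_dmr_called) == 0) 0 else
      sum(m$is_dmr_called & !m$is_dmr_true) / sum(m$is_dmr_called)
  )
}
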