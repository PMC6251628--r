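test_that("CpG table round-trip, zero-coverage drops and malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  cpgs <- tibble::tibble(chrom = "chr1", start = c(100L, 200L, 300L),
                         end = c(101L, 201L, 301L),
                         meth_count = c(7L, 0L, 5L), unmeth_count = c(3L, 12L, 0L))
  write_cpg_table(as_cpg_calls(cpgs), f)
  back <- read_cpg_table(f)
  expect_equal(back$methylation, c(0.7, 0.0, 1.0))
  expect_equal(back$coverage, c(10L, 12L, 5L))

  zero <- dplyr::mutate(cpgs, unmeth_count = c(3L, 12L, 0L), meth_count = c(7L, 0L, 0L))
  expect_warning(dropped <- as_cpg_calls(zero), "zero coverage")
  expect_equal(nrow(dropped), 2)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tmeth_count\tunmeth_count",
               "chr1\t100\t101\t7\t3", "chr1\tnot_a_number\t201\t2\t2"), bad)
  # the bad record sits on physical file line 3 (line 1 is the header)
  expect_error(suppressWarnings(read_cpg_table(bad)), "line 3")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tstart\tend\tmeth_count\tunmeth_count", empty)
  expect_warning(e <- read_cpg_table(empty), "empty")
  expect_equal(nrow(e), 0)
})

test_that("strand merging sums symmetric-CpG counts", {
  raw <- tibble::tibble(chrom = "chr1", start = c(100L, 101L, 300L),
                        end = c(101L, 102L, 301L), strand = c("+", "-", "+"),
                        meth_count = c(3L, 2L, 1L), unmeth_count = c(1L, 4L, 9L))
  merged <- merge_cpg_strands(raw)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$meth_count[merged$start == 100], 5L)
  expect_equal(merged$coverage[merged$start == 100], 10L)
})

test_that("weighted median follows the lower-median expansion convention", {
  expect_equal(weighted_median(c(0.1, 0.5, 0.9), c(10, 10, 10)), 0.5)
  # cumulative weight 30 >= 40/2 at the first value
  expect_equal(weighted_median(c(0.0, 1.0), c(30, 10)), 0.0)
  expect_equal(weighted_median(0.42, 7), 0.42)
  expect_error(weighted_median(numeric(), numeric()), "empty")
  expect_error(weighted_median(c(1, 2), c(1, -1)), "positive")

  set.seed(3)
  for (i in 1:200) {
    n <- sample(1:15, 1)
    v <- round(runif(n), 3)
    w <- sample(1:40, n, replace = TRUE)
    expect_equal(weighted_median(v, w), oracle_weighted_median(v, w))
    # equal weights reduce to the ordinary lower median
    expect_equal(weighted_median(v, rep(5, n)), oracle_weighted_median(v, rep(1, n)))
  }
})

test_that("feature methylation enforces the 2-CpG / 5x rule", {
  feature <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L,
                            feature_id = "f1")
  one_cpg <- tibble::tibble(chrom = "chr1", start = 10L, end = 11L,
                            meth_count = 10L, unmeth_count = 10L)
  r1 <- feature_methylation(as_cpg_calls(one_cpg), feature)
  expect_equal(r1$status, "insufficient_data")
  expect_true(is.na(r1$value))

  three <- tibble::tibble(chrom = "chr1", start = c(10L, 20L, 30L), end = c(11L, 21L, 31L),
                          meth_count = c(0L, 2L, 10L), unmeth_count = c(10L, 8L, 0L))
  r3 <- feature_methylation(as_cpg_calls(three), feature)
  expect_equal(r3$status, "called")
  expect_equal(r3$value, oracle_weighted_median(c(0, 0.2, 1), c(10, 10, 10)))
  expect_equal(r3$value, 0.2)

  low_cov <- tibble::tibble(chrom = "chr1", start = c(10L, 20L), end = c(11L, 21L),
                            meth_count = c(2L, 2L), unmeth_count = c(2L, 2L))
  expect_equal(feature_methylation(as_cpg_calls(low_cov), feature)$status,
               "insufficient_data")

  # CpGs outside the feature never contribute
  outside <- tibble::tibble(chrom = "chr1", start = c(10L, 20L, 5000L),
                            end = c(11L, 21L, 5001L),
                            meth_count = c(10L, 10L, 0L), unmeth_count = c(0L, 0L, 10L))
  ro <- feature_methylation(as_cpg_calls(outside), feature)
  expect_equal(ro$n_cpgs_used, 2L)
  expect_equal(ro$value, 1)
})

test_that("tile methylation uses the coverage-weighted mean and pairs conditions", {
  cpgs <- as_cpg_calls(tibble::tibble(
    chrom = "chr1", start = c(10L, 60L, 150L), end = c(11L, 61L, 151L),
    meth_count = c(0L, 30L, 5L), unmeth_count = c(10L, 0L, 5L)))
  tiles <- tile_methylation(cpgs, tile_size = 100)
  # tile [0,100): weighted mean of 0.0@10x and 1.0@30x = 0.75
  expect_equal(tiles$value[tiles$start == 0], 0.75)
  # tile [100,200) has a single qualifying CpG: no call
  expect_false(100 %in% tiles$start)

  paired <- tile_methylation(cpgs, tile_size = 100, cpgs_b = cpgs)
  expect_true(all(paired$delta == 0))
})

test_that("feature values are monotone under raising every CpG's methylation", {
  set.seed(9)
  feature <- tibble::tibble(chrom = "chr1", start = 0L, end = 500L)
  for (i in 1:25) {
    cov <- sample(5:40, 8, replace = TRUE)
    meth <- vapply(cov, function(k) sample(0:k, 1), integer(1))
    base <- tibble::tibble(chrom = "chr1", start = seq(10L, 80L, by = 10L),
                           end = seq(11L, 81L, by = 10L),
                           meth_count = meth, unmeth_count = cov - meth)
    raised <- dplyr::mutate(base, meth_count = pmin(meth_count + 3L, meth_count + unmeth_count),
                            unmeth_count = (base$meth_count + base$unmeth_count) - meth_count)
    v0 <- feature_methylation(as_cpg_calls(base), feature)$value
    v1 <- feature_methylation(as_cpg_calls(raised), feature)$value
    expect_gte(v1, v0)
    expect_true(v0 >= 0 && v0 <= 1 && v1 >= 0 && v1 <= 1)
  }
})
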