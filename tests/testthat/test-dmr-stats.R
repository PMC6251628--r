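test_that("weighted t-test handles identical, degenerate and invalid input", {
  x <- c(0.1, 0.4, 0.6)
  w <- c(10, 20, 30)
  same <- weighted_t_test(x, w, x, w)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  flat <- weighted_t_test(c(0.5, 0.5), c(10, 20), c(0.5, 0.5), c(5, 5))
  expect_equal(flat$p_value, 1)

  deg <- weighted_t_test(c(0, 0), c(10, 10), c(1, 1), c(10, 10))
  expect_equal(deg$status, "degenerate")
  expect_equal(deg$p_value, 0)

  expect_error(weighted_t_test(0.5, 10, c(0.2, 0.3), c(5, 5)), "at least 2")
  expect_error(weighted_t_test(c(0.1, 0.2), c(1, 0), c(0.2, 0.3), c(5, 5)), "positive")
})

test_that("equal weights reduce to the standard Welch test", {
  set.seed(14)
  for (i in 1:100) {
    na <- sample(3:20, 1)
    nb <- sample(3:20, 1)
    a <- runif(na)
    b <- runif(nb, 0, runif(1, 0.5, 1.5))
    ours <- weighted_t_test(a, rep(7, na), b, rep(3, nb))
    ref <- t.test(a, b)
    expect_lt(abs(ours$p_value - ref$p.value), 1e-9)
    expect_equal(abs(ours$t_stat), abs(ref$statistic[[1]]), tolerance = 1e-9)
    expect_equal(ours$df, ref$parameter[[1]], tolerance = 1e-6)
  }
})

test_that("swapping condition labels negates diffs and preserves p-values", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    a <- runif(n); wa <- sample(5:50, n, replace = TRUE)
    b <- runif(n); wb <- sample(5:50, n, replace = TRUE)
    ab <- weighted_t_test(a, wa, b, wb)
    ba <- weighted_t_test(b, wb, a, wa)
    expect_equal(ab$diff, -ba$diff)
    expect_equal(ab$p_value, ba$p_value)
  }
})

test_that("q-values follow the Storey/BH machinery", {
  expect_equal(as.numeric(storey_q_values(rep(1, 10))), rep(1, 10))

  # BH by hand: p * m / rank, monotonized from the tail
  p <- c(0.01, 0.02, 0.03, 0.04)
  q <- storey_q_values(p, pi0_method = "bh")
  expect_equal(as.numeric(q), rep(0.04, 4))
  expect_equal(attr(q, "pi0"), 1)

  set.seed(16)
  p_rand <- runif(300)
  expect_equal(as.numeric(storey_q_values(p_rand, pi0_method = "bh")),
               p.adjust(p_rand, "BH"))

  # pi0 under a uniform null is close to 1; Storey q never exceeds BH by design
  p_null <- runif(10000)
  q_st <- storey_q_values(p_null)
  expect_gte(attr(q_st, "pi0"), 0.9)
  expect_lte(attr(q_st, "pi0"), 1.0)
  expect_true(all(q_st <= p.adjust(p_null, "BH") + 1e-12))

  # monotone non-decreasing in sorted p order
  o <- order(p_rand)
  expect_true(all(diff(storey_q_values(p_rand)[o]) >= -1e-12))

  expect_error(storey_q_values(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DMR calling respects thresholds, direction and symmetry", {
  sim <- simulate_rrbs_pair(sim_config(seed = 31, n_regions = 300,
                                       dmr_fraction = 0.1, dmr_effect = 0.3))
  d <- call_dmrs(sim$condition_a, sim$condition_b, sim$regions)
  expect_s3_class(d, "dmr_result")
  expect_equal(nrow(d), 300)

  unreachable <- call_dmrs(sim$condition_a, sim$condition_b, sim$regions,
                           diff_thresh = 1.1)
  expect_equal(sum(unreachable$is_dmr), 0)

  swapped <- call_dmrs(sim$condition_b, sim$condition_a, sim$regions)
  expect_equal(swapped$diff, -d$diff)
  expect_equal(swapped$p_value, d$p_value)

  gain <- call_dmrs(sim$condition_a, sim$condition_b, sim$regions, direction = "gain")
  expect_true(all(gain$diff[gain$is_dmr] >= 0.2))

  # starving a region of coverage marks it untestable and shrinks the family
  thin_a <- sim$condition_a[-(1:9), ]
  d2 <- call_dmrs(thin_a, sim$condition_b, sim$regions)
  expect_equal(d2$status[1], "insufficient_data")
  expect_true(is.na(d2$q_value[1]))
  expect_equal(sum(!is.na(d2$p_value)), 299)
})

test_that("hypergeometric overlap matches exhaustive enumeration", {
  expect_equal(hypergeometric_overlap(10, 5, 5, 5), 1 / choose(10, 5))
  expect_equal(hypergeometric_overlap(10, 5, 5, 0), 1)
  expect_error(hypergeometric_overlap(10, 5, 5, 6), "overlap")
  expect_error(hypergeometric_overlap(10, 12, 5, 2), "universe")

  for (ov in 0:6) {
    expect_equal(hypergeometric_overlap(12, 6, 6, ov), oracle_hypergeom(12, 6, 6, ov))
  }
  for (ov in c(0, 3, 5, 8)) {
    expect_equal(hypergeometric_overlap(16, 8, 8, ov), oracle_hypergeom(16, 8, 8, ov))
  }
  # overlap at the rounded-down expectation keeps p >= 0.5 in symmetric cases
  expect_gte(hypergeometric_overlap(20, 10, 10, 5), 0.5)
})

test_that("expression stratification bins DMR promoters", {
  dmrs <- tibble::tibble(gene_id = paste0("g", 1:100),
                         is_dmr = c(rep(TRUE, 10), rep(FALSE, 90)))
  expr <- tibble::tibble(gene_id = paste0("g", 1:100),
                         expression = c(runif(10, 0, 0.5), runif(90, 1, 10)))
  out <- stratify_by_expression(dmrs, expr, bins = 4)
  expect_equal(sum(out$n_dmr), 10)
  expect_equal(out$n_dmr[1], 10) # all DMRs in the lowest expression class

  none <- stratify_by_expression(dplyr::mutate(dmrs, is_dmr = FALSE), expr, bins = 4)
  expect_true(all(none$n_dmr == 0))

  expect_warning(stratify_by_expression(dmrs, expr[1:50, ], bins = 2), "without expression")

  # uniform random assignment spreads evenly over quantile bins
  set.seed(40)
  dmr_u <- tibble::tibble(gene_id = paste0("g", 1:2000),
                          is_dmr = sample(c(TRUE, FALSE), 2000, replace = TRUE, prob = c(0.3, 0.7)))
  expr_u <- tibble::tibble(gene_id = paste0("g", 1:2000), expression = runif(2000))
  out_u <- stratify_by_expression(dmr_u, expr_u, bins = 5)
  chisq <- suppressWarnings(chisq.test(out_u$n_dmr)$p.value)
  expect_gt(chisq, 0.01)
})
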