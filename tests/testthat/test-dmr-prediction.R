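mk_prediction_inputs <- function(n = 200, seed = 51) {
  withr::with_seed(seed, {
    ids <- sprintf("cgi_%04d", seq_len(n))
    list(
      rpkm = tibble::tibble(cgi_id = ids,
                            h3k4me3 = rexp(n, 0.2), h3k27me3 = rexp(n, 0.5),
                            h3k36me3 = rexp(n, 1), dnase = rexp(n, 0.3)),
      feats = tibble::tibble(cgi_id = ids, cpg_density = runif(n, 0.04, 0.12),
                             normalized_cpg_density = runif(n, 0.6, 0.9),
                             gc_fraction = runif(n, 0.5, 0.7)),
      meth = tibble::tibble(cgi_id = ids, control_methylation = runif(n, 0, 0.4))
    )
  })
}

test_that("feature matrix applies the percentile, log, z-score and methylation rules", {
  inp <- mk_prediction_inputs()
  fm <- build_feature_matrix(inp$rpkm, inp$feats, inp$meth)
  expect_true(all(fm$control_methylation < 0.2))
  for (tr in c("h3k4me3", "h3k27me3", "h3k36me3", "dnase")) {
    expect_lt(abs(mean(fm[[tr]])), 1e-10)
    expect_equal(sd(fm[[tr]]), 1, tolerance = 1e-10)
  }

  # the 99th-percentile rule removes the top CGIs of each track before scaling
  spiked <- inp$rpkm
  spiked$h3k4me3[1:3] <- 1e5
  fm2 <- build_feature_matrix(spiked, inp$feats, inp$meth)
  expect_false(any(fm2$cgi_id %in% spiked$cgi_id[1:3]))
  fm2w <- build_feature_matrix(spiked, inp$feats, inp$meth,
                               percentile_action = "winsorize")
  expect_true(nrow(fm2w) > nrow(fm2))

  # log(0 + 0.001) = -6.9078 on the natural scale before z-scoring
  expect_equal(log(0 + 0.001), -6.907755, tolerance = 1e-6)

  const <- dplyr::mutate(inp$rpkm, h3k36me3 = 2.5)
  fm3 <- build_feature_matrix(const, inp$feats, inp$meth)
  expect_true(all(fm3$h3k36me3 == 0)) # sd-zero guard

  over <- dplyr::mutate(inp$meth, control_methylation = 0.25)
  expect_equal(nrow(build_feature_matrix(inp$rpkm, inp$feats, over)), 0)
})

test_that("PR curves match the brute-force threshold sweep", {
  set.seed(52)
  for (i in 1:5) {
    n <- sample(50:400, 1)
    labels <- runif(n) < 0.3
    scores <- runif(n) + labels * runif(1, 0, 1)
    if (i == 3) scores <- round(scores, 1) # force heavy ties
    pr <- pr_curve(scores, labels)
    orc <- oracle_pr(scores, labels)
    expect_equal(pr$curve$threshold, orc$threshold)
    expect_equal(pr$curve$precision, orc$precision)
    expect_equal(pr$curve$recall, orc$recall)
  }

  perfect <- pr_curve(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$recall_at_fdr5, 1)
  expect_equal(perfect$auc_pr, 1)

  # duplicating every observation leaves the curve unchanged
  set.seed(53)
  labels <- runif(300) < 0.2
  scores <- runif(300) + labels
  one <- pr_curve(scores, labels)
  two <- pr_curve(rep(scores, 2), rep(labels, 2))
  expect_equal(one$curve$precision, two$curve$precision)
  expect_equal(one$auc_pr, two$auc_pr)

  # random scores: precision hovers at prevalence, AUC-PR -> prevalence
  set.seed(54)
  labels_r <- runif(5000) < 0.1
  rand <- pr_curve(runif(5000), labels_r)
  expect_lt(abs(rand$auc_pr - 0.1), 0.03)
  expect_equal(rand$recall_at_fdr5, 0)
})

test_that("classifier training is deterministic and validates labels", {
  ft <- simulate_feature_table(sim_config(seed = 55), 300)
  m1 <- train_classifier(ft, "random_forest", seed = 9)
  m2 <- train_classifier(ft, "random_forest", seed = 9)
  expect_equal(predict(m1, ft), predict(m2, ft))

  single <- dplyr::mutate(ft, label = TRUE)
  expect_error(train_classifier(single, "random_forest"), "single class")

  # a perfectly separable table is learned to training recall 1 at precision >= 0.95
  sep <- tibble::tibble(x1 = c(rnorm(150, -3), rnorm(50, 3)),
                        x2 = rnorm(200),
                        label = rep(c(FALSE, TRUE), c(150, 50)))
  fit <- train_classifier(sep, "random_forest", seed = 1)
  expect_equal(pr_curve(predict(fit, sep), sep$label)$recall_at_fdr5, 1)
})

test_that("every classifier backend returns usable scores", {
  ft <- simulate_feature_table(sim_config(seed = 56), 250)
  for (m in c("random_forest", "logistic", "naive_bayes", "decision_tree",
              "gradient_boosting")) {
    fit <- train_classifier(ft, m, seed = 3)
    s <- predict(fit, ft)
    expect_length(s, nrow(ft))
    expect_true(all(s >= 0 & s <= 1), info = m)
    # better than chance on its own training data
    expect_gt(pr_curve(s, ft$label)$auc_pr, mean(ft$label), label = m)
  }
})

test_that("cross-validation stratifies folds and pools out-of-fold scores", {
  ft <- simulate_feature_table(sim_config(seed = 57), 400)
  pr <- cross_validated_pr(ft, method = "logistic", k = 5, seed = 2)
  folds <- pr$folds
  expect_setequal(unique(folds), 1:5)
  per_fold_pos <- tapply(ft$label, folds, sum)
  expect_lte(diff(range(per_fold_pos)), 1)
  expect_equal(nrow(pr$scores), 400)

  tiny <- ft[c(which(ft$label)[1:3], which(!ft$label)[1:50]), ]
  expect_error(cross_validated_pr(tiny, k = 5, seed = 1), "fewer members")
})

test_that("label permutation destroys out-of-fold performance", {
  ft <- simulate_feature_table(sim_config(seed = 58), 500)
  perm <- withr::with_seed(59, dplyr::mutate(ft, label = sample(label)))
  pr <- cross_validated_pr(perm, method = "logistic", k = 5, seed = 2)
  expect_lt(pr$auc_pr, mean(perm$label) + 0.1)
  expect_lt(pr$recall_at_fdr5, 0.05)
})

test_that("ablation reuses identical folds across features", {
  ft <- simulate_feature_table(sim_config(seed = 60), 300)
  ab <- feature_ablation(ft, method = "logistic", k = 5, seed = 4)
  expect_equal(nrow(ab$ranking), 8)
  for (pr in ab$ablations) expect_identical(pr$folds, ab$full$folds)
  expect_identical(ab$folds, ab$full$folds)
  expect_s3_class(tidy(ab), "tbl_df")
})
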