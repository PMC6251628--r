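#' Build the eight-feature CGI predictor table
#'
#' Assembles, per CpG island, the signal and sequence features used to
#' predict hypermethylation susceptibility. Per signal track the CGIs above
#' that track's 99th RPKM percentile are removed (or winsorized), RPKM is
#' transformed as `log(RPKM + 0.001)` and standardized to a z-score over the
#' retained set; only CGIs with control methylation below `meth_threshold`
#' (canonical unmethylated islands) are retained. Filtering precedes
#' normalization.
#'
#' @param track_rpkm Tibble with `cgi_id` and one RPKM column per signal
#'   track (typically `h3k4me3`, `h3k27me3`, `h3k36me3`, `dnase`).
#' @param cgi_features Tibble with `cgi_id`, `cpg_density`,
#'   `normalized_cpg_density`, `gc_fraction` (from [detect_cgis()] output).
#' @param control_methylation Tibble with `cgi_id`, `control_methylation`.
#' @param labels Optional tibble with `cgi_id` and logical `label`.
#' @param meth_threshold Retain only CGIs with control methylation strictly
#'   below this value.
#' @param rpkm_percentile Upper filtering quantile per track.
#' @param percentile_action `"drop"` (remove those CGIs) or `"winsorize"`
#'   (cap at the percentile).
#' @param log_base `"natural"` or `"log10"`.
#' @return A tibble: `cgi_id`, z-scored track columns, sequence features,
#'   `control_methylation`, and `label` when supplied.
#' @export
build_feature_matrix <- function(track_rpkm, cgi_features, control_methylation,
                                 labels = NULL, meth_threshold = 0.2,
                                 rpkm_percentile = 0.99,
                                 percentile_action = c("drop", "winsorize"),
                                 log_base = c("natural", "log10")) {
  percentile_action <- match.arg(percentile_action)
  log_base <- match.arg(log_base)
  stopifnot("cgi_id" %in% names(track_rpkm),
            all(c("cgi_id") %in% names(cgi_features)),
            all(c("cgi_id", "control_methylation") %in% names(control_methylation)))
  n0 <- nrow(track_rpkm)
  df <- track_rpkm |>
    dplyr::inner_join(cgi_features, by = "cgi_id") |>
    dplyr::inner_join(control_methylation, by = "cgi_id")
  if (nrow(df) < n0) {
    message(n0 - nrow(df), " CGI(s) dropped for missing annotation or methylation")
  }
  tracks <- setdiff(names(track_rpkm), "cgi_id")
  for (tr in tracks) {
    cutoff <- stats::quantile(df[[tr]], rpkm_percentile, names = FALSE)
    if (percentile_action == "drop") {
      df <- df[df[[tr]] < cutoff, , drop = FALSE]
    } else {
      df[[tr]] <- pmin(df[[tr]], cutoff)
    }
  }
  df <- df[df$control_methylation < meth_threshold, , drop = FALSE]
  logf <- if (log_base == "natural") log else log10
  for (tr in tracks) {
    x <- logf(df[[tr]] + 0.001)
    s <- stats::sd(x)
    df[[tr]] <- if (is.finite(s) && s > 0) (x - mean(x)) / s else x * 0
  }
  if (!is.null(labels)) {
    df <- dplyr::inner_join(df, labels[, c("cgi_id", "label")], by = "cgi_id")
  }
  tibble::as_tibble(df)
}

#' Train a DMR-susceptibility classifier
#'
#' Fits one of five classifiers to a labelled feature table. The random
#' forest uses 100 trees with class weights `c(1, nneg/npos)`; gradient
#' boosting uses binary logistic loss, depth 10, 10 rounds, subsample 0.7 and
#' positive-class weight `nneg/npos`; the remaining methods use their
#' package defaults.
#'
#' @param data Tibble of numeric features plus a logical/binary label column.
#' @param method One of `"random_forest"`, `"logistic"`, `"naive_bayes"`,
#'   `"decision_tree"`, `"gradient_boosting"`.
#' @param seed Integer seed making the fit deterministic.
#' @param label_col Name of the label column.
#' @return An object of class `"methylhet_model"`.
#' @export
train_classifier <- function(data, method = c("random_forest", "logistic",
                                              "naive_bayes", "decision_tree",
                                              "gradient_boosting"),
                             seed = 1L, label_col = "label") {
  method <- match.arg(method)
  stopifnot(label_col %in% names(data))
  y <- as.integer(as.logical(data[[label_col]]))
  if (length(unique(y)) < 2) stop("labels contain a single class", call. = FALSE)
  feats <- setdiff(names(data), c(label_col, "cgi_id"))
  x <- as.data.frame(data[, feats, drop = FALSE])
  npos <- sum(y == 1)
  nneg <- sum(y == 0)
  yf <- factor(y, levels = c(0, 1))
  fit <- withr::with_seed(seed, switch(method,
    random_forest = randomForest::randomForest(
      x = x, y = yf, ntree = 100, classwt = c("0" = 1, "1" = nneg / npos)),
    logistic = stats::glm(y ~ ., data = cbind(x, y = y), family = stats::binomial()),
    naive_bayes = e1071::naiveBayes(x = x, y = yf),
    decision_tree = rpart::rpart(y ~ ., data = cbind(x, y = yf), method = "class"),
    gradient_boosting = xgboost::xgboost(
      as.matrix(x), yf, objective = "binary:logistic", max_depth = 10,
      nrounds = 10, subsample = 0.7, scale_pos_weight = nneg / npos,
      nthreads = 1, verbosity = 0)
  ))
  structure(list(fit = fit, method = method, features = feats,
                 label_col = label_col, seed = seed,
                 n_pos = npos, n_neg = nneg),
            class = "methylhet_model")
}

#' Predicted positive-class probabilities
#'
#' @param object A `"methylhet_model"`.
#' @param newdata Tibble containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict.methylhet_model <- function(object, newdata, ...) {
  x <- as.data.frame(newdata[, object$features, drop = FALSE])
  switch(object$method,
    random_forest = unname(stats::predict(object$fit, x, type = "prob")[, "1"]),
    logistic = unname(stats::predict(object$fit, x, type = "response")),
    naive_bayes = unname(stats::predict(object$fit, x, type = "raw")[, "1"]),
    decision_tree = unname(stats::predict(object$fit, x)[, "1"]),
    gradient_boosting = unname(stats::predict(object$fit, as.matrix(x)))
  )
}

#' @export
glance.methylhet_model <- function(x, ...) {
  tibble::tibble(method = x$method, n_features = length(x$features),
                 n_pos = x$n_pos, n_neg = x$n_neg, seed = x$seed)
}

#' Precision-recall curve from scores
#'
#' Sweeps all score thresholds (descending); at each threshold precision and
#' recall are computed over the predictions at or above it, with tied scores
#' entering together. `recall_at_fdr5` is the recall of the highest-recall
#' point with precision of at least `1 - fdr` (0 when never reached), reading
#' a 5% false-discovery operating point as precision >= 0.95.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical/binary truth labels.
#' @param fdr Target false discovery rate of the reported operating point.
#' @return An object of class `"pr_curve"`: `curve` (tibble `threshold`,
#'   `precision`, `recall`), `auc_pr` (step-interpolated area, the average
#'   precision), `recall_at_fdr5`, `n`, `n_pos`.
#' @export
pr_curve <- function(scores, labels, fdr = 0.05) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels)) stop("no positive labels", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  tp <- cumsum(y)
  n_pred <- seq_along(y)
  # keep the last index of each tied-score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  precision <- tp[last] / n_pred[last]
  recall <- tp[last] / sum(y)
  curve <- tibble::tibble(threshold = s[last], precision = precision, recall = recall)
  auc <- sum(diff(c(0, recall)) * precision)
  ok <- precision >= 1 - fdr
  r5 <- if (any(ok)) max(recall[ok]) else 0
  structure(list(curve = curve, auc_pr = auc, recall_at_fdr5 = r5,
                 n = length(y), n_pos = sum(y)),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat("<pr_curve> n =", x$n, " positives =", x$n_pos, "\n")
  cat("  AUC-PR:", round(x$auc_pr, 4),
      " recall at precision >= 0.95:", round(x$recall_at_fdr5, 4), "\n")
  invisible(x)
}

#' @export
tidy.pr_curve <- function(x, ...) x$curve

#' @export
glance.pr_curve <- function(x, ...) {
  tibble::tibble(auc_pr = x$auc_pr, recall_at_fdr5 = x$recall_at_fdr5,
                 n = x$n, n_pos = x$n_pos)
}

# deterministic stratified fold assignment
stratified_folds <- function(labels, k, seed) {
  labels <- as.logical(labels)
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < k) {
        stop("class ", cls, " has fewer members (", length(idx),
             ") than folds (", k, ")", call. = FALSE)
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Cross-validated precision-recall evaluation
#'
#' Stratified k-fold cross-validation: the classifier is trained on each
#' training split and scores the held-out fold; out-of-fold scores are pooled
#' into a single precision-recall curve.
#'
#' @inheritParams train_classifier
#' @param k Number of folds.
#' @param folds Optional precomputed fold assignment (for paired
#'   comparisons); overrides `k`/`seed` fold generation.
#' @return A `"pr_curve"` with extra elements `folds` (assignment vector),
#'   `scores` (tibble `row`, `fold`, `score`, `label`) and `method`.
#' @export
cross_validated_pr <- function(data, method = "random_forest", k = 5L, seed = 1L,
                               label_col = "label", folds = NULL) {
  y <- as.logical(data[[label_col]])
  if (is.null(folds)) folds <- stratified_folds(y, k, seed)
  stopifnot(length(folds) == nrow(data))
  scores <- numeric(nrow(data))
  for (f in sort(unique(folds))) {
    test <- folds == f
    fit <- train_classifier(data[!test, , drop = FALSE], method = method,
                            seed = seed + f, label_col = label_col)
    scores[test] <- predict(fit, data[test, , drop = FALSE])
  }
  out <- pr_curve(scores, y)
  out$folds <- folds
  out$scores <- tibble::tibble(row = seq_along(scores), fold = folds,
                               score = scores, label = y)
  out$method <- method
  out
}

#' Leave-one-feature-out ablation
#'
#' Re-runs the cross-validated evaluation with each feature removed in turn,
#' using the same folds and seed as the all-features model (paired
#' comparison), and ranks features by the performance drop their removal
#' causes.
#'
#' @inheritParams cross_validated_pr
#' @return An object of class `"feature_ablation"`: `full` (the all-features
#'   `"pr_curve"`), `ablations` (named list of `"pr_curve"`), and `ranking`
#'   (tibble `feature`, `auc_pr`, `delta_auc_pr`, `recall_at_fdr5`,
#'   `delta_recall_at_fdr5`, sorted by performance drop).
#' @export
feature_ablation <- function(data, method = "random_forest", k = 5L, seed = 1L,
                             label_col = "label") {
  feats <- setdiff(names(data), c(label_col, "cgi_id"))
  if (length(feats) < 2) stop("at least 2 features required", call. = FALSE)
  y <- as.logical(data[[label_col]])
  folds <- stratified_folds(y, k, seed)
  full <- cross_validated_pr(data, method = method, seed = seed,
                             label_col = label_col, folds = folds)
  ablations <- purrr::map(rlang::set_names(feats), function(f) {
    cross_validated_pr(data[, setdiff(names(data), f), drop = FALSE],
                       method = method, seed = seed,
                       label_col = label_col, folds = folds)
  })
  ranking <- purrr::imap(ablations, function(pr, f) {
    tibble::tibble(feature = f, auc_pr = pr$auc_pr,
                   delta_auc_pr = full$auc_pr - pr$auc_pr,
                   recall_at_fdr5 = pr$recall_at_fdr5,
                   delta_recall_at_fdr5 = full$recall_at_fdr5 - pr$recall_at_fdr5)
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(dplyr::desc(.data$delta_auc_pr))
  structure(list(full = full, ablations = ablations, ranking = ranking,
                 method = method, folds = folds),
            class = "feature_ablation")
}

#' @export
print.feature_ablation <- function(x, ...) {
  cat("<feature_ablation>", x$method, "- full AUC-PR",
      round(x$full$auc_pr, 4), "\n")
  print(x$ranking)
  invisible(x)
}

#' @export
tidy.feature_ablation <- function(x, ...) x$ranking

#' @export
glance.feature_ablation <- function(x, ...) {
  tibble::tibble(method = x$method, n_features = nrow(x$ranking),
                 full_auc_pr = x$full$auc_pr,
                 full_recall_at_fdr5 = x$full$recall_at_fdr5,
                 top_feature = x$ranking$feature[1])
}
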