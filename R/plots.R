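#' Plot a precision-recall curve
#'
#' @param object A `"pr_curve"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh", color = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed", color = "grey50") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  subtitle = sprintf("AUC-PR %.3f; recall %.3f at precision ≥ 0.95",
                                     object$auc_pr, object$recall_at_fdr5)) +
    ggplot2::theme_minimal()
}

#' Plot feature-ablation precision-recall curves
#'
#' Overlays the all-features curve with each leave-one-feature-out curve.
#'
#' @param object A `"feature_ablation"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_ablation <- function(object, ...) {
  abl <- purrr::imap(object$ablations, function(pr, f) {
    dplyr::mutate(pr$curve, removed = f)
  }) |> dplyr::bind_rows()
  full <- dplyr::mutate(object$full$curve, removed = "none (all features)")
  ggplot2::ggplot(abl, ggplot2::aes(x = .data$recall, y = .data$precision,
                                    color = .data$removed)) +
    ggplot2::geom_step(direction = "vh", alpha = 0.8) +
    ggplot2::geom_step(data = full, direction = "vh",
                       color = "black", linewidth = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", color = "Feature removed") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential methylation results
#'
#' @param object A `"dmr_result"` from [call_dmrs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmr_result <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$p_value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diff,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   color = .data$is_dmr)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "#d7301f")) +
    ggplot2::labs(x = "Methylation difference (B - A)",
                  y = expression(-log[10] ~ p), color = "DMR") +
    ggplot2::theme_minimal()
}

#' Plot the epiallele spectrum
#'
#' Distinct epialleles per number of methylated CpGs per molecule.
#'
#' @param summary An `"epiallele_summary"` from [count_epialleles()], or a
#'   named list of them (one panel series per sample).
#' @return A ggplot object.
#' @export
plot_epiallele_spectrum <- function(summary) {
  if (inherits(summary, "epiallele_summary")) summary <- list(sample = summary)
  df <- purrr::imap(summary, function(s, nm) dplyr::mutate(s$per_k, sample = nm)) |>
    dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$n_epialleles,
                                   color = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Methylated CpGs per molecule",
                  y = "Distinct epialleles", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot in-phase CpG correlation against genomic distance
#'
#' @param corr Tibble from [phase_correlation()].
#' @return A ggplot object.
#' @export
plot_phase_correlation <- function(corr) {
  ggplot2::ggplot(corr, ggplot2::aes(x = .data$bin_mid, y = .data$mean_r)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::scale_size_continuous(range = c(0.5, 3)) +
    ggplot2::labs(x = "Pairwise CpG distance (bp)", y = "Mean in-phase correlation",
                  size = "CpG pairs") +
    ggplot2::theme_minimal()
}

#' Plot a composite TSS profile
#'
#' @param profile Tibble from [composite_profile()].
#' @param value_label y-axis label.
#' @return A ggplot object.
#' @export
plot_composite_profile <- function(profile, value_label = "Mean signal") {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin_mid, y = .data$value,
                                        color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = "Distance from TSS (bp)", y = value_label, color = NULL) +
    ggplot2::theme_minimal()
}
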