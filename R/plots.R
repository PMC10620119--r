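#' Enrichment plot for one metric
#'
#' Bounded enrichment percentage against -log10 permutation FDR, with dashed
#' guides at the ratio threshold (mapped onto the percentage scale via
#' `100 r / (1 + r)`) and at the FDR threshold; hits drawn in red.
#'
#' @param results A `pdl_comparison` tibble.
#' @param metric `"pa"` or `"psm"`.
#' @param contrast Contrast to plot.
#' @param thresholds A [filter_thresholds()] for the guide lines.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, metric = "pa", contrast = "bait_vs_ctrl",
                            thresholds = filter_thresholds()) {
  sl <- results[results$metric == metric & results$contrast == contrast, ]
  sl <- sl[!is.na(sl$enrichment_pct) & !is.na(sl$fdr), ]
  sl$hit_like <- !is.na(sl$ratio) & sl$ratio >= thresholds$min_ratio &
    sl$fdr <= thresholds$max_fdr
  pct_line <- 100 * thresholds$min_ratio / (1 + thresholds$min_ratio)
  ggplot2::ggplot(sl, ggplot2::aes(
    x = .data$enrichment_pct,
    y = -log10(pmax(.data$fdr, 1e-4)),
    colour = .data$hit_like
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = pct_line, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(thresholds$max_fdr), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"), guide = "none") +
    ggplot2::labs(
      x = "Enrichment (%), 100 * bait / (bait + control)",
      y = expression(-log[10] ~ "permutation FDR"),
      title = sprintf("%s enrichment, %s", toupper(metric), contrast)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pdl_pca <- function(object, ...) {
  ve <- attr(object, "var_explained")
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$PC1, y = .data$PC2,
    colour = .data$group, shape = factor(.data$experiment)
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * ve[2]),
      shape = "experiment",
      title = sprintf("Run-level PCA (%s)", toupper(attr(object, "metric")))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pdl_funnel <- function(object, ...) {
  object$step <- factor(object$step, levels = object$step)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$step, y = .data$n_remaining)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_remaining), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "proteins remaining", title = "Hit-filter funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.pdl_calibration <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = log2(.data$cutoff))) +
    ggplot2::geom_segment(ggplot2::aes(
      xend = log2(.data$cutoff),
      y = .data$fitted, yend = .data$known_count
    ), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$known_count)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::geom_vline(xintercept = log2(object$suggested_cutoff), linetype = "dashed") +
    ggplot2::labs(
      x = "log2 ratio cutoff", y = "known interactors recovered",
      title = sprintf(
        "Known-interactor recovery (%s); suggested cutoff %.2f",
        toupper(object$metric), object$suggested_cutoff
      )
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of stratified p-values or FDRs
#'
#' @param x A `pdl_pval_strata` or `pdl_fdr_strata` object.
#' @return A ggplot object.
#' @export
plot_strata_histogram <- function(x) {
  h <- x$histogram
  by_col <- names(h)[1]
  ggplot2::ggplot(h, ggplot2::aes(
    x = .data$bin_lo + (.data$bin_hi - .data$bin_lo) / 2,
    y = .data$count, fill = .data[[by_col]]
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "value", y = "count", fill = by_col) +
    ggplot2::theme_minimal()
}
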