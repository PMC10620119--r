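#' Log-transform a quantification layer
#'
#' Zeros are structural non-detections in PDL data, not small measurements, so
#' they become `NA` ("missing") rather than `-Inf`; downstream tests exclude
#' them from sample sizes while untransformed group means retain them.
#'
#' @param q A [quant_table()].
#' @param metric `"pa"` or `"psm"`.
#' @param base Logarithm base, 2 or 10.
#' @return Numeric matrix, same shape as the layer, `NA` where the value was 0.
#' @export
log_transform <- function(q, metric = c("pa", "psm"), base = 2) {
  metric <- match.arg(metric)
  stopifnot(base %in% c(2, 10))
  m <- q[[metric]]
  out <- suppressWarnings(log(m, base = base))
  out[m == 0] <- NA_real_
  out
}

contrast_groups <- function(contrast = c("bait_vs_ctrl", "bait_vs_wt")) {
  contrast <- match.arg(contrast)
  switch(contrast,
    bait_vs_ctrl = c("BAIT", "LIGASE_CTRL"),
    bait_vs_wt = c("BAIT", "WILDTYPE")
  )
}

## Row-wise pooled-variance two-sample t on a matrix with NAs.
## Returns tibble(t_stat, df, p_one_tailed, n_used_bait, n_used_ctrl, status);
## one-tailed alternative is mean(bait) > mean(ctrl).
row_t_onetailed <- function(logvals, bait_cols, ctrl_cols) {
  xb <- logvals[, bait_cols, drop = FALSE]
  xc <- logvals[, ctrl_cols, drop = FALSE]
  nb <- rowSums(!is.na(xb))
  nc <- rowSums(!is.na(xc))
  mb <- rowMeans(xb, na.rm = TRUE)
  mc <- rowMeans(xc, na.rm = TRUE)
  ssb <- rowSums((xb - mb)^2, na.rm = TRUE)
  ssc <- rowSums((xc - mc)^2, na.rm = TRUE)
  df <- nb + nc - 2
  sp2 <- (ssb + ssc) / pmax(df, 1)
  se <- sqrt(sp2 * (1 / nb + 1 / nc))
  t <- (mb - mc) / se
  p <- suppressWarnings(pt(t, df, lower.tail = FALSE))
  status <- rep("ok", nrow(logvals))

  untestable <- nb < 2 | nc < 2
  degenerate <- !untestable & sp2 == 0
  ## zero pooled variance: direction of the mean difference decides
  diff <- mb - mc
  t[degenerate] <- sign(diff[degenerate]) * Inf
  t[degenerate & diff == 0] <- 0
  p[degenerate] <- ifelse(diff[degenerate] > 0, 0, ifelse(diff[degenerate] < 0, 1, 0.5))
  status[degenerate] <- "degenerate"
  t[untestable] <- NA_real_
  p[untestable] <- NA_real_
  df[untestable] <- NA_real_
  status[untestable] <- "untestable"

  tibble::tibble(
    t_stat = unname(t), df = unname(df), p_one_tailed = unname(p),
    n_used_bait = unname(nb), n_used_ctrl = unname(nc), status = status
  )
}

#' One-tailed Student's t-test per protein
#'
#' Pooled-variance two-sample t-test on log-transformed values, with the
#' one-tailed alternative that the bait group mean exceeds the control group
#' mean (p = P(T_df >= t)). Zeros were turned into `NA` by [log_transform()]
#' and are excluded; a protein with fewer than 2 non-missing values in either
#' group is flagged `"untestable"` (statistics `NA`). Zero-pooled-variance
#' cases are flagged `"degenerate"`: p = 0.5 for equal means, 0 when the bait
#' mean is larger, 1 when smaller.
#'
#' @param logvals Matrix from [log_transform()].
#' @param design Run design tibble matching the matrix columns.
#' @param contrast `"bait_vs_ctrl"` or `"bait_vs_wt"`.
#' @return Tibble: `accession`, `t_stat`, `df`, `p_one_tailed`,
#'   `n_used_bait`, `n_used_ctrl`, `status`.
#' @export
one_tailed_t_test <- function(logvals, design, contrast = "bait_vs_ctrl") {
  gg <- contrast_groups(contrast)
  res <- row_t_onetailed(
    logvals,
    bait_cols = which(design$group == gg[1]),
    ctrl_cols = which(design$group == gg[2])
  )
  dplyr::bind_cols(tibble::tibble(accession = rownames(logvals)), res)
}

#' Untransformed group-mean ratio per protein
#'
#' Ratio of the bait group mean to the control group mean of the raw
#' (untransformed) metric, zeros included — the convention under which a
#' protein never labeled by the control gets ratio `Inf` (passing any finite
#' cutoff) and a protein absent from both groups gets `NA` (failing it).
#'
#' @inheritParams log_transform
#' @param contrast `"bait_vs_ctrl"` or `"bait_vs_wt"`.
#' @return Tibble: `accession`, `mean_bait`, `mean_ctrl`, `ratio`.
#' @export
group_ratio <- function(q, metric = c("pa", "psm"), contrast = "bait_vs_ctrl") {
  metric <- match.arg(metric)
  gg <- contrast_groups(contrast)
  m <- q[[metric]]
  mb <- rowMeans(m[, q$design$group == gg[1], drop = FALSE])
  mc <- rowMeans(m[, q$design$group == gg[2], drop = FALSE])
  ratio <- ifelse(mc > 0, mb / mc, ifelse(mb > 0, Inf, NA_real_))
  tibble::tibble(
    accession = rownames(m),
    mean_bait = unname(mb), mean_ctrl = unname(mc), ratio = unname(ratio)
  )
}

#' Bounded enrichment percentage per protein
#'
#' `100 * mean_bait / (mean_bait + mean_ctrl)` on untransformed group means —
#' a bounded alternative to pseudocount ratios that keeps proteins with zero
#' control signal (100%) on the scale. `NA` when both means are zero.
#'
#' @inheritParams group_ratio
#' @return Tibble: `accession`, `enrichment_pct`.
#' @export
enrichment_percent <- function(q, metric = c("pa", "psm"), contrast = "bait_vs_ctrl") {
  r <- group_ratio(q, metric, contrast)
  denom <- r$mean_bait + r$mean_ctrl
  tibble::tibble(
    accession = r$accession,
    enrichment_pct = ifelse(denom > 0, 100 * r$mean_bait / denom, NA_real_)
  )
}

#' Full bait-vs-control comparison on one or both metrics
#'
#' The central statistics step: for each requested metric and contrast,
#' computes untransformed group means, ratio, enrichment percentage, the
#' one-tailed pooled-variance t-test on log2 values, and the permutation-based
#' FDR. FDR is estimated separately per metric and per contrast (no
#' cross-metric pooling).
#'
#' @param q A [quant_table()].
#' @param metrics Character vector among `"pa"`, `"psm"`.
#' @param contrasts Character vector among `"bait_vs_ctrl"`, `"bait_vs_wt"`.
#' @param perm A [perm_config()] controlling the permutation FDR.
#' @param base Log base for the transform (default 2).
#' @return Tibble of class `pdl_comparison`, one row per protein x metric x
#'   contrast, with columns `accession`, `symbol`, `metric`, `contrast`,
#'   `mean_bait`, `mean_ctrl`, `ratio`, `enrichment_pct`, `t_stat`, `df`,
#'   `p_one_tailed`, `fdr`, `n_used_bait`, `n_used_ctrl`, `status`.
#' @export
#' @examples
#' sim <- simulate_pdl_experiment(sim_config(n_proteins = 60, seed = 3))
#' res <- compare_groups(sim$quant, perm = perm_config(n_permutations = 30))
#' dplyr::count(res, metric, contrast)
compare_groups <- function(q,
                           metrics = c("pa", "psm"),
                           contrasts = c("bait_vs_ctrl", "bait_vs_wt"),
                           perm = perm_config(),
                           base = 2) {
  stopifnot(inherits(q, "pdl_quant"))
  metrics <- match.arg(metrics, c("pa", "psm"), several.ok = TRUE)
  grid <- tidyr::expand_grid(metric = metrics, contrast = contrasts)
  out <- purrr::pmap(grid, function(metric, contrast) {
    logvals <- log_transform(q, metric, base = base)
    tt <- one_tailed_t_test(logvals, q$design, contrast)
    tt$fdr <- permutation_fdr(tt, logvals, q$design, contrast, perm)
    rr <- group_ratio(q, metric, contrast)
    ep <- enrichment_percent(q, metric, contrast)
    dplyr::bind_cols(
      tibble::tibble(
        accession = q$proteins$accession,
        symbol = q$proteins$symbol,
        metric = metric,
        contrast = contrast
      ),
      rr[c("mean_bait", "mean_ctrl", "ratio")],
      ep["enrichment_pct"],
      tt[c("t_stat", "df", "p_one_tailed", "fdr", "n_used_bait", "n_used_ctrl", "status")]
    )
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("pdl_comparison", class(out))
  attr(out, "perm") <- perm
  out
}

#' Run-level principal component diagnostics
#'
#' PCA of the runs on log-transformed values with missing entries imputed to
#' the observed minimum (a conservative stand-in for "below detection").
#' In a well-behaved PDL experiment the first components separate cell lines
#' and experiments.
#'
#' @inheritParams log_transform
#' @return Tibble of class `pdl_pca`: one row per run with the design columns,
#'   `PC1`, `PC2`; attributes `var_explained` (length-2 numeric) and
#'   `degenerate` (TRUE when fewer than 2 informative proteins).
#' @export
pca_diagnostics <- function(q, metric = c("pa", "psm"), base = 2) {
  stopifnot(inherits(q, "pdl_quant"), nrow(q$design) >= 3)
  logvals <- log_transform(q, metric, base = base)
  obs_min <- suppressWarnings(min(logvals, na.rm = TRUE))
  if (!is.finite(obs_min)) obs_min <- 0
  logvals[is.na(logvals)] <- obs_min
  keep <- apply(logvals, 1, function(x) var(x) > 0)
  degenerate <- sum(keep) < 2
  out <- q$design
  if (degenerate) {
    out$PC1 <- 0
    out$PC2 <- 0
    ve <- c(NA_real_, NA_real_)
    warn("Fewer than 2 informative proteins; PCA is degenerate")
  } else {
    pc <- prcomp(t(logvals[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
    out$PC1 <- unname(pc$x[, 1])
    out$PC2 <- if (ncol(pc$x) >= 2) unname(pc$x[, 2]) else 0
    ve <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  }
  out <- tibble::as_tibble(out)
  class(out) <- c("pdl_pca", class(out))
  attr(out, "var_explained") <- ve
  attr(out, "degenerate") <- degenerate
  attr(out, "metric") <- match.arg(metric)
  out
}
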