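#' Default calibration cutoff grid
#'
#' 21 geometrically spaced ratio cutoffs from 1.0 to 4.0, spanning the range
#' over which PDL enrichment cutoffs are normally debated.
#'
#' @return Numeric vector of length 21.
#' @export
calibration_grid <- function() {
  2^seq(0, 2, length.out = 21)
}

#' Known-interactor recovery versus ratio cutoff
#'
#' The retrospective cutoff-calibration analysis: for each candidate ratio
#' cutoff, counts how many database-curated partners of the bait are retained
#' at `ratio >= cutoff`, fits `count ~ log2(cutoff)` by least squares, and
#' suggests the grid cutoff whose observed count is closest to the fitted
#' line (ties broken toward the smaller cutoff). A cutoff "close to the line"
#' marks the elbow where recovery starts to decay smoothly rather than
#' cliff-dropping.
#'
#' @param results A `pdl_comparison` tibble from [compare_groups()].
#' @param known An [interactor_set()] of curated partners.
#' @param grid Strictly increasing positive cutoffs; default
#'   [calibration_grid()].
#' @param metric,contrast Which statistics slice to calibrate on.
#' @return Object of class `pdl_calibration`: list with `curve` (tibble:
#'   `cutoff`, `known_count`, `fitted`, `residual`), `slope`, `intercept`,
#'   `suggested_cutoff`, `degenerate`, `metric`.
#' @export
#' @examples
#' sim <- simulate_pdl_experiment(sim_config(n_proteins = 80, seed = 5))
#' res <- compare_groups(sim$quant,
#'   contrasts = "bait_vs_ctrl",
#'   perm = perm_config(n_permutations = 25)
#' )
#' known <- simulate_annotation(sim$truth, seed = 5)
#' cal <- known_recovery_curve(res, known)
#' cal$suggested_cutoff
known_recovery_curve <- function(results, known,
                                 grid = calibration_grid(),
                                 metric = "pa", contrast = "bait_vs_ctrl") {
  if (!length(grid)) abort("Cutoff grid is empty")
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE)) {
    abort("Cutoff grid must be strictly increasing and positive")
  }
  sl <- results[results$metric == metric & results$contrast == contrast, ]
  is_known <- toupper(sl$symbol) %in% toupper(known$partners)
  kr <- sl$ratio[is_known]
  counts <- vapply(grid, function(g) sum(!is.na(kr) & kr >= g), integer(1))

  degenerate <- length(kr) == 0 || length(unique(counts)) == 1
  if (degenerate) {
    slope <- NA_real_
    intercept <- NA_real_
    fit_vals <- rep(if (length(counts)) counts[1] else NA_real_, length(grid))
  } else {
    fit <- lm(counts ~ log2(grid))
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    fit_vals <- unname(fitted(fit))
  }
  residual <- counts - fit_vals
  suggested <- grid[which.min(abs(residual))] # which.min: first = smallest cutoff
  structure(
    list(
      curve = tibble::tibble(
        cutoff = grid, known_count = counts,
        fitted = fit_vals, residual = residual
      ),
      slope = slope, intercept = intercept,
      suggested_cutoff = suggested,
      degenerate = degenerate,
      metric = metric, contrast = contrast,
      n_known_in_results = sum(is_known)
    ),
    class = "pdl_calibration"
  )
}

#' @export
print.pdl_calibration <- function(x, ...) {
  cat(sprintf(
    "<pdl_calibration> %s/%s: %d known interactors in results; suggested cutoff %.3g%s\n",
    x$metric, x$contrast, x$n_known_in_results, x$suggested_cutoff,
    if (x$degenerate) " (degenerate fit)" else ""
  ))
  invisible(x)
}

#' FDR distribution stratified by known-interactor status
#'
#' Compares the permutation-FDR distribution of database-curated partners of
#' the bait against all other proteins. In a well-behaved experiment the known
#' stratum is shifted toward low FDR — the basis for choosing the FDR cutoff
#' retrospectively.
#'
#' @inheritParams known_recovery_curve
#' @param threshold FDR threshold reported as a passing fraction
#'   (default 0.05).
#' @param bin_width Histogram bin width on [0, 1] (default 0.05).
#' @return List of class `pdl_fdr_strata` with `summary` (tibble: `stratum`,
#'   `n`, `q25`, `median`, `q75`, `frac_le_threshold`) and `histogram`
#'   (tibble: `stratum`, `bin_lo`, `bin_hi`, `count`).
#' @export
fdr_density_by_annotation <- function(results, known,
                                      metric = "pa", contrast = "bait_vs_ctrl",
                                      threshold = 0.05, bin_width = 0.05) {
  sl <- results[results$metric == metric & results$contrast == contrast, ]
  sl$stratum <- ifelse(toupper(sl$symbol) %in% toupper(known$partners), "known", "unknown")
  if (!any(sl$stratum == "known")) {
    warn("No curated partner appears in the results; known stratum is empty")
  }
  strata_summary <- sl |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n = sum(!is.na(.data$fdr)),
      q25 = quantile(.data$fdr, 0.25, na.rm = TRUE, names = FALSE),
      median = quantile(.data$fdr, 0.5, na.rm = TRUE, names = FALSE),
      q75 = quantile(.data$fdr, 0.75, na.rm = TRUE, names = FALSE),
      frac_le_threshold =
        if (any(!is.na(.data$fdr))) mean(.data$fdr <= threshold, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    )
  hist <- histogram_by(sl, "fdr", "stratum", bin_width)
  structure(
    list(summary = strata_summary, histogram = hist, threshold = threshold),
    class = "pdl_fdr_strata"
  )
}

histogram_by <- function(df, value_col, by_col, bin_width = 0.05) {
  breaks <- seq(0, 1, by = bin_width)
  df <- df[!is.na(df[[value_col]]), ]
  df$bin <- cut(pmin(pmax(df[[value_col]], 0), 1),
    breaks = breaks, include.lowest = TRUE, labels = FALSE
  )
  grid <- tidyr::expand_grid(
    .by = unique(df[[by_col]]),
    bin = seq_len(length(breaks) - 1)
  )
  names(grid)[1] <- by_col
  counts <- df |>
    dplyr::count(.data[[by_col]], .data$bin, name = "count")
  out <- dplyr::left_join(grid, counts, by = c(by_col, "bin"))
  out$count[is.na(out$count)] <- 0L
  out$bin_lo <- breaks[out$bin]
  out$bin_hi <- breaks[out$bin + 1]
  out[, c(by_col, "bin_lo", "bin_hi", "count")]
}

#' P-value distribution stratified by minimum average bait PSM
#'
#' Diagnoses how quantification reliability depends on spectral evidence:
#' histograms of the one-tailed PA p-values under progressively stricter
#' minimum-average-bait-PSM-per-injection rules, plus the proportion of
#' proteins at p <= 0.05 per rule. Restricting to proteins with at least 1
#' average PSM per injection typically raises that proportion.
#'
#' @param results A `pdl_comparison` tibble.
#' @param q The [quant_table()] (source of bait PSM counts).
#' @param rules Tibble of stratification rules (`label`, `threshold`,
#'   `strict`); a strict rule requires `avg > threshold`, otherwise
#'   `avg >= threshold`. Default: `>= 0` (all), `> 0`, `>= 1`.
#' @param metric,contrast Statistics slice to stratify (default PA,
#'   bait-vs-control).
#' @param bin_width Histogram bin width on [0, 1].
#' @return List of class `pdl_pval_strata` with `summary` (tibble: `rule`,
#'   `n`, `prop_le_0.05`) and `histogram` (tibble: `rule`, `bin_lo`,
#'   `bin_hi`, `count`). Empty strata are kept with `n = 0`.
#' @export
pvalue_distribution_by_psm <- function(results, q,
                                       rules = psm_rules(),
                                       metric = "pa", contrast = "bait_vs_ctrl",
                                       bin_width = 0.05) {
  sl <- results[results$metric == metric & results$contrast == contrast, ]
  bait_runs <- q$design$group == "BAIT"
  avg <- rowSums(q$psm[, bait_runs, drop = FALSE]) / sum(bait_runs)
  sl$avg_bait_psm <- avg[match(sl$accession, rownames(q$psm))]
  per_rule <- purrr::pmap(rules, function(label, threshold, strict) {
    keep <- if (strict) sl$avg_bait_psm > threshold else sl$avg_bait_psm >= threshold
    sub <- sl[keep & !is.na(sl$p_one_tailed), ]
    list(
      summary = tibble::tibble(
        rule = label,
        n = nrow(sub),
        prop_le_0.05 = if (nrow(sub)) mean(sub$p_one_tailed <= 0.05) else NA_real_
      ),
      histogram = if (nrow(sub)) {
        sub$rule <- label
        histogram_by(sub, "p_one_tailed", "rule", bin_width)
      } else {
        tibble::tibble(
          rule = character(0), bin_lo = numeric(0),
          bin_hi = numeric(0), count = integer(0)
        )
      }
    )
  })
  structure(
    list(
      summary = dplyr::bind_rows(purrr::map(per_rule, "summary")),
      histogram = dplyr::bind_rows(purrr::map(per_rule, "histogram"))
    ),
    class = "pdl_pval_strata"
  )
}

#' Default PSM stratification rules
#'
#' @return Tibble with columns `label`, `threshold`, `strict` describing the
#'   rules `>= 0`, `> 0` and `>= 1` on average bait PSM per injection.
#' @export
psm_rules <- function() {
  tibble::tibble(
    label = c(">=0", ">0", ">=1"),
    threshold = c(0, 0, 1),
    strict = c(FALSE, TRUE, FALSE)
  )
}
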