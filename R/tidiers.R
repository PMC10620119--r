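#' Tidy a calibration object
#'
#' @param x A `pdl_calibration` from [known_recovery_curve()].
#' @param ... Unused.
#' @return The cutoff-grid curve as a tibble (`cutoff`, `known_count`,
#'   `fitted`, `residual`).
#' @export
tidy.pdl_calibration <- function(x, ...) {
  x$curve
}

#' One-row summary of a calibration object
#'
#' @inheritParams tidy.pdl_calibration
#' @return Tibble with `slope`, `intercept`, `suggested_cutoff`,
#'   `n_known_in_results`, `degenerate`.
#' @export
glance.pdl_calibration <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept,
    suggested_cutoff = x$suggested_cutoff,
    n_known_in_results = x$n_known_in_results,
    degenerate = x$degenerate
  )
}

#' One-row summary of a hit table
#'
#' @param x A `pdl_hits` from [call_hits()].
#' @param ... Unused.
#' @return Tibble with protein and hit counts, the thresholds used, and the
#'   known-interactor overlap if annotated.
#' @export
glance.pdl_hits <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble::tibble(
    n_proteins = nrow(x),
    n_hits = sum(x$is_hit),
    n_known_hits = attr(x, "n_known_hits") %||% NA_integer_,
    min_ratio = th$min_ratio,
    max_fdr = th$max_fdr,
    min_avg_psm = th$min_avg_psm_per_injection,
    require_wt = th$require_wt_contrast
  )
}

#' One-row summary of a PCA diagnostic
#'
#' @param x A `pdl_pca` from [pca_diagnostics()].
#' @param ... Unused.
#' @return Tibble with the variance explained by the first two components.
#' @export
glance.pdl_pca <- function(x, ...) {
  ve <- attr(x, "var_explained")
  tibble::tibble(
    metric = attr(x, "metric"),
    pc1_var_explained = ve[1],
    pc2_var_explained = ve[2],
    degenerate = attr(x, "degenerate")
  )
}

#' Tidy a depth stratification
#'
#' @param x A `pdl_depths` from [degree_stratify()].
#' @param ... Unused.
#' @return Per-stratum counts as a tibble (`stratum`, `n`).
#' @export
tidy.pdl_depths <- function(x, ...) {
  attr(x, "counts")
}
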