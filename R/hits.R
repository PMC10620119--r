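#' Hit-calling thresholds
#'
#' The hit definition for a PDL/MS experiment: a protein is a hit when its
#' bait-vs-control ratio is at least `min_ratio` with permutation FDR at most
#' `max_fdr` on *both* quantification metrics (peak area and PSM), and its
#' average bait-group PSM per injection is at least
#' `min_avg_psm_per_injection`. With `require_wt_contrast = TRUE` the
#' ratio/FDR criteria must also hold against the wildtype contrast.
#'
#' The wildtype contrast is off by default: in a labeling experiment with
#' negligible wildtype biotinylation most proteins have too few nonzero
#' wildtype values for any t-test, so an FDR requirement against wildtype
#' rejects proteins for having *maximal* evidence of enrichment. The wildtype
#' arm is better used as the qualitative negligibility check; the switch
#' remains for designs where wildtype labeling is substantial.
#'
#' @param min_ratio Minimum untransformed group-mean ratio (default 1.5, the
#'   TurboID/BioID field-standard enrichment cutoff).
#' @param max_fdr Maximum permutation FDR (default 0.05).
#' @param min_avg_psm_per_injection Minimum average bait PSM per injection
#'   (default 1).
#' @param require_wt_contrast Also require the criteria against wildtype
#'   (default FALSE).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_ratio = 1.5, max_fdr = 0.05,
                              min_avg_psm_per_injection = 1,
                              require_wt_contrast = FALSE) {
  stopifnot(min_ratio > 0, max_fdr > 0, max_fdr <= 1, min_avg_psm_per_injection >= 0)
  structure(
    list(
      min_ratio = min_ratio, max_fdr = max_fdr,
      min_avg_psm_per_injection = min_avg_psm_per_injection,
      require_wt_contrast = isTRUE(require_wt_contrast)
    ),
    class = "filter_thresholds"
  )
}

#' Call hits from comparison statistics
#'
#' Applies the multi-criterion hit definition of [filter_thresholds()] to a
#' [compare_groups()] result. Conventions: an infinite ratio (no control
#' signal) passes the ratio criterion, an undefined ratio (absent from both
#' groups) fails it, and untestable proteins fail the FDR criteria.
#'
#' @param results A `pdl_comparison` tibble from [compare_groups()]; must
#'   carry both metrics for `bait_vs_ctrl` (and `bait_vs_wt` when the
#'   wildtype contrast is required).
#' @param q The [quant_table()] the statistics came from (for bait PSM).
#' @param thresholds A [filter_thresholds()].
#' @return Tibble of class `pdl_hits`, one row per protein: statistics in
#'   wide form (`pa_ratio`, `pa_fdr`, `psm_ratio`, `psm_fdr`,
#'   `pa_enrichment_pct`, `avg_bait_psm`, ...), one logical `pass_*` flag per
#'   criterion, and `is_hit` (their conjunction). Thresholds are attached as
#'   the `"thresholds"` attribute.
#' @export
#' @examples
#' sim <- simulate_pdl_experiment(sim_config(n_proteins = 60, seed = 3))
#' res <- compare_groups(sim$quant, perm = perm_config(n_permutations = 30))
#' hits <- call_hits(res, sim$quant)
#' sum(hits$is_hit)
call_hits <- function(results, q, thresholds = filter_thresholds()) {
  stopifnot(inherits(q, "pdl_quant"), inherits(thresholds, "filter_thresholds"))
  need_contrasts <- c("bait_vs_ctrl", if (thresholds$require_wt_contrast) "bait_vs_wt")
  for (ct in need_contrasts) {
    for (mt in c("pa", "psm")) {
      if (!any(results$metric == mt & results$contrast == ct)) {
        abort(sprintf("`results` lacks metric \"%s\" for contrast \"%s\"", mt, ct))
      }
    }
  }
  wide <- results |>
    dplyr::filter(.data$contrast %in% need_contrasts) |>
    dplyr::mutate(
      key = paste0(
        .data$metric,
        ifelse(.data$contrast == "bait_vs_wt", "_wt", "")
      )
    ) |>
    dplyr::select(
      "accession", "symbol", "key", "ratio", "fdr", "enrichment_pct",
      "p_one_tailed", "status"
    ) |>
    tidyr::pivot_wider(
      id_cols = c("accession", "symbol"),
      names_from = "key",
      values_from = c("ratio", "fdr", "enrichment_pct", "p_one_tailed", "status"),
      names_glue = "{key}_{.value}"
    )

  bait_runs <- q$design$group == "BAIT"
  psm_tbl <- tibble::tibble(
    accession = rownames(q$psm),
    avg_bait_psm = unname(rowSums(q$psm[, bait_runs, drop = FALSE]) / sum(bait_runs))
  )
  out <- dplyr::left_join(wide, psm_tbl, by = "accession")

  pass_ratio <- function(r) !is.na(r) & r >= thresholds$min_ratio
  pass_fdr <- function(f) !is.na(f) & f <= thresholds$max_fdr
  out$pass_pa_ratio <- pass_ratio(out$pa_ratio)
  out$pass_pa_fdr <- pass_fdr(out$pa_fdr)
  out$pass_psm_ratio <- pass_ratio(out$psm_ratio)
  out$pass_psm_fdr <- pass_fdr(out$psm_fdr)
  out$pass_min_psm <- out$avg_bait_psm >= thresholds$min_avg_psm_per_injection
  flags <- c(
    "pass_pa_ratio", "pass_pa_fdr", "pass_psm_ratio", "pass_psm_fdr",
    "pass_min_psm"
  )
  if (thresholds$require_wt_contrast) {
    out$pass_pa_ratio_wt <- pass_ratio(out$pa_wt_ratio)
    out$pass_pa_fdr_wt <- pass_fdr(out$pa_wt_fdr)
    out$pass_psm_ratio_wt <- pass_ratio(out$psm_wt_ratio)
    out$pass_psm_fdr_wt <- pass_fdr(out$psm_wt_fdr)
    flags <- c(flags, "pass_pa_ratio_wt", "pass_pa_fdr_wt", "pass_psm_ratio_wt", "pass_psm_fdr_wt")
  }
  out$is_hit <- Reduce(`&`, out[flags])
  class(out) <- c("pdl_hits", class(out))
  attr(out, "thresholds") <- thresholds
  attr(out, "flags") <- flags
  out
}

#' Filter funnel: survivor counts per criterion
#'
#' Applies the pass flags of a hit table cumulatively in the given order and
#' reports how many proteins survive each step. The first row (`"all"`) is the
#' table size; because the hit definition is a conjunction, the final count is
#' invariant to the order.
#'
#' @param hits A `pdl_hits` tibble from [call_hits()].
#' @param order Character vector of flag column names; defaults to all flags
#'   in their natural order.
#' @return Tibble of class `pdl_funnel`: `step`, `n_remaining`.
#' @export
filter_funnel <- function(hits, order = attr(hits, "flags")) {
  stopifnot(inherits(hits, "pdl_hits"))
  order <- order %||% character(0)
  unknown <- setdiff(order, names(hits))
  if (length(unknown)) {
    abort(paste0("Unknown criterion flag(s): ", paste(unknown, collapse = ", ")))
  }
  alive <- rep(TRUE, nrow(hits))
  n <- integer(length(order) + 1)
  n[1] <- nrow(hits)
  for (i in seq_along(order)) {
    alive <- alive & hits[[order[i]]]
    n[i + 1] <- sum(alive)
  }
  out <- tibble::tibble(step = c("all", order), n_remaining = n)
  class(out) <- c("pdl_funnel", class(out))
  out
}

#' Rank a hit table by a statistic
#'
#' Stable sort of a hit table, descending by default (so the bait protein
#' itself, typically the most labeled by average bait PSM, ranks first) and
#' ascending for FDR/p-value keys.
#'
#' @param hits A `pdl_hits` tibble.
#' @param key Column to sort by (e.g. `"avg_bait_psm"`, `"pa_ratio"`,
#'   `"pa_fdr"`).
#' @param decreasing Sort direction; default `NULL` picks descending except
#'   for keys containing `"fdr"` or `"p_one_tailed"`.
#' @param hits_only Keep only rows with `is_hit` (default TRUE).
#' @return The reordered tibble.
#' @export
rank_hits <- function(hits, key = "avg_bait_psm", decreasing = NULL, hits_only = TRUE) {
  if (!key %in% names(hits)) abort(paste0("Unknown ranking key: ", key))
  if (is.null(decreasing)) {
    decreasing <- !grepl("fdr|p_one_tailed", key)
  }
  out <- if (hits_only) dplyr::filter(hits, .data$is_hit) else hits
  idx <- order(out[[key]], decreasing = decreasing, method = "radix")
  out[idx, ]
}
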