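#' Permutation configuration
#'
#' Settings for the permutation-based FDR of [permutation_fdr()] /
#' [compare_groups()]. When the number of distinct group-label splits of the
#' contrast's runs is at most `exhaustive_limit`, all splits are enumerated
#' and the estimate is deterministic (seed-independent); otherwise
#' `n_permutations` random splits are drawn under `seed`. The default limit
#' keeps the 9-vs-9 design (48620 splits) on random permutations; raise it to
#' force exhaustive enumeration.
#'
#' @param n_permutations Number of random label permutations (default 250).
#' @param exhaustive_limit Enumerate all splits when their count is at most
#'   this (default 20000).
#' @param s0 Fudge factor added to the denominator of the t-statistic
#'   (SAM-style); 0 disables it.
#' @param seed Integer seed for the random-permutation mode.
#' @return A list of class `perm_config`.
#' @export
perm_config <- function(n_permutations = 250, exhaustive_limit = 20000,
                        s0 = 0, seed = 1L) {
  stopifnot(n_permutations >= 1, exhaustive_limit >= 1, s0 >= 0)
  structure(
    list(
      n_permutations = as.integer(n_permutations),
      exhaustive_limit = as.integer(exhaustive_limit),
      s0 = s0,
      seed = as.integer(seed)
    ),
    class = "perm_config"
  )
}

## t statistics (one-tailed direction: pseudo-bait minus pseudo-ctrl) for one
## label split, on the rows where the observed test was valid. s0 per SAM.
perm_t_stats <- function(logvals, bait_cols, ctrl_cols, s0 = 0) {
  xb <- logvals[, bait_cols, drop = FALSE]
  xc <- logvals[, ctrl_cols, drop = FALSE]
  nb <- rowSums(!is.na(xb))
  nc <- rowSums(!is.na(xc))
  mb <- rowMeans(xb, na.rm = TRUE)
  mc <- rowMeans(xc, na.rm = TRUE)
  ss <- rowSums((xb - mb)^2, na.rm = TRUE) + rowSums((xc - mc)^2, na.rm = TRUE)
  sp2 <- ss / pmax(nb + nc - 2, 1)
  se <- sqrt(sp2 * (1 / nb + 1 / nc)) + s0
  t <- (mb - mc) / se
  diff <- mb - mc
  zerovar <- is.finite(diff) & se == 0
  t[zerovar] <- sign(diff[zerovar]) * Inf
  t[zerovar & diff == 0] <- 0
  t[nb < 2 | nc < 2] <- NA_real_
  unname(t)
}

#' Permutation-based FDR for one-tailed enrichment statistics
#'
#' Estimates, for each protein's observed one-tailed t statistic used as a
#' threshold, `FDR(t) = (mean number of permutation statistics >= t) /
#' (number of observed statistics >= t)`, where permutation statistics are
#' recomputed after permuting the bait/control labels of the contrast's runs.
#' Estimates are monotonized so FDR is non-increasing in the statistic
#' (running minimum from the smallest statistic upward) and clipped to
#' [0, 1]. Untestable proteins get `NA` and never enter the counts.
#'
#' All `choose(n, n_bait)` label splits are enumerated when that count is at
#' most `cfg$exhaustive_limit` (deterministic); otherwise `cfg$n_permutations`
#' random splits are drawn under `cfg$seed`.
#'
#' @param t_obs Result tibble of [one_tailed_t_test()] (needs `t_stat`,
#'   `status`).
#' @param logvals Log-value matrix the test was run on.
#' @param design Run design tibble.
#' @param contrast `"bait_vs_ctrl"` or `"bait_vs_wt"`.
#' @param cfg A [perm_config()].
#' @return Numeric vector of FDR values aligned with `t_obs` rows.
#' @export
permutation_fdr <- function(t_obs, logvals, design, contrast = "bait_vs_ctrl",
                            cfg = perm_config()) {
  gg <- contrast_groups(contrast)
  cols <- which(design$group %in% gg)
  n_bait <- sum(design$group == gg[1])
  n_tot <- length(cols)
  if (n_tot < 3 || n_bait < 1 || n_bait >= n_tot) {
    abort("Too few runs in the contrast to permute group labels")
  }
  sub <- logvals[, cols, drop = FALSE]

  testable <- t_obs$status != "untestable" & !is.na(t_obs$t_stat)
  if (!any(testable)) {
    return(rep(NA_real_, nrow(t_obs)))
  }
  tt <- t_obs$t_stat[testable]

  n_splits <- choose(n_tot, n_bait)
  if (n_splits <= cfg$exhaustive_limit) {
    splits <- combn(n_tot, n_bait, simplify = FALSE)
  } else {
    splits <- withr::with_seed(
      cfg$seed,
      replicate(cfg$n_permutations, sort(sample.int(n_tot, n_bait)), simplify = FALSE)
    )
  }

  ## count, per observed threshold, permutation statistics >= threshold
  ord <- order(tt, decreasing = TRUE)
  thresholds <- tt[ord]
  sub_testable <- sub[testable, , drop = FALSE]
  exceed <- numeric(length(thresholds))
  for (sp in splits) {
    ts <- perm_t_stats(sub_testable,
      bait_cols = sp, ctrl_cols = setdiff(seq_len(n_tot), sp),
      s0 = cfg$s0
    )
    ts <- ts[!is.na(ts)]
    if (!length(ts)) next
    ## number of ts >= each threshold (thresholds sorted descending)
    srt <- sort(ts) # ascending
    exceed <- exceed + (length(srt) - findInterval(thresholds, srt, left.open = TRUE))
  }
  mean_fp <- exceed / length(splits)
  srt_obs <- sort(thresholds)
  obs_pos <- length(srt_obs) - findInterval(thresholds, srt_obs, left.open = TRUE)
  raw <- mean_fp / obs_pos
  q <- pmin(rev(cummin(rev(raw))), 1)

  fdr <- rep(NA_real_, nrow(t_obs))
  fdr[which(testable)[ord]] <- q
  fdr
}
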