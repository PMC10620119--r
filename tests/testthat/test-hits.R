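## Hand-built comparison table for 6 proteins, bait-vs-ctrl only.
toy_results <- function(q, pa_ratio, pa_fdr, psm_ratio, psm_fdr, status = "ok") {
  n <- nrow(q$proteins)
  base <- tibble::tibble(
    accession = q$proteins$accession, symbol = q$proteins$symbol,
    contrast = "bait_vs_ctrl",
    mean_bait = 1, mean_ctrl = 1,
    enrichment_pct = 50, t_stat = 1, df = 4, p_one_tailed = 0.1,
    n_used_bait = 3, n_used_ctrl = 3, status = status
  )
  out <- dplyr::bind_rows(
    dplyr::mutate(base, metric = "pa", ratio = pa_ratio, fdr = pa_fdr),
    dplyr::mutate(base, metric = "psm", ratio = psm_ratio, fdr = psm_fdr)
  )
  class(out) <- c("pdl_comparison", class(out))
  out
}

test_that("call_hits evaluates the criterion conjunction like a hand tally", {
  psm <- matrix(rep(c(6L, 6L, 6L, 0L, 3L, 2L), each = 6), 6, 6, byrow = TRUE)
  q <- toy_quant(matrix(4, 6, 6), psm = psm)
  ## protein:        1     2     3    4    5     6
  pa_ratio <- c(2.0, 1.4, Inf, 3.0, 2.0, NA)
  pa_fdr <- c(0.01, 0.01, 0.02, 0.20, 0.01, NA)
  psm_ratio <- c(1.6, 2.0, 5.0, 2.0, 1.6, NA)
  psm_fdr <- c(0.04, 0.04, 0.00, 0.01, 0.04, NA)
  ## avg bait PSM:    6     6     6    0    3     2
  res <- toy_results(q, pa_ratio, pa_fdr, psm_ratio, psm_fdr)
  hits <- call_hits(res, q, filter_thresholds())
  th <- filter_thresholds()
  manual <- vapply(1:6, function(i) {
    isTRUE(pa_ratio[i] >= th$min_ratio) && isTRUE(pa_fdr[i] <= th$max_fdr) &&
      isTRUE(psm_ratio[i] >= th$min_ratio) && isTRUE(psm_fdr[i] <= th$max_fdr) &&
      mean(psm[i, 1:3]) >= th$min_avg_psm_per_injection
  }, logical(1))
  expect_identical(hits$is_hit[match(q$proteins$accession, hits$accession)], manual)
  expect_identical(manual, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  ## infinite ratio passes; undefined ratio fails; untestable fails FDR
  expect_true(hits$pass_pa_ratio[3])
  expect_false(hits$pass_pa_ratio[6])
  expect_false(hits$pass_pa_fdr[6])
})

test_that("vacuous thresholds make every defined protein a hit", {
  sim <- simulate_pdl_experiment(sim_config(n_proteins = 80, seed = 44))
  res <- compare_groups(sim$quant,
    contrasts = "bait_vs_ctrl",
    perm = perm_config(n_permutations = 30, seed = 1)
  )
  th <- filter_thresholds(
    min_ratio = 1e-9, max_fdr = 1,
    min_avg_psm_per_injection = 0
  )
  hits <- call_hits(res, sim$quant, th)
  defined <- !is.na(hits$pa_ratio) & !is.na(hits$pa_fdr) &
    !is.na(hits$psm_ratio) & !is.na(hits$psm_fdr)
  expect_identical(hits$is_hit, defined)
  expect_gt(sum(hits$is_hit), 0)
})

test_that("missing required contrast is an error", {
  sim <- simulate_pdl_experiment(sim_config(n_proteins = 30, seed = 1))
  res <- compare_groups(sim$quant,
    contrasts = "bait_vs_ctrl",
    perm = perm_config(n_permutations = 10)
  )
  expect_error(
    call_hits(res, sim$quant, filter_thresholds(require_wt_contrast = TRUE)),
    "bait_vs_wt"
  )
})

test_that("filter funnel counts survivors cumulatively and order-invariantly", {
  psm <- matrix(rep(c(6L, 6L, 6L, 0L, 3L, 2L), each = 6), 6, 6, byrow = TRUE)
  q <- toy_quant(matrix(4, 6, 6), psm = psm)
  res <- toy_results(
    q,
    pa_ratio = c(2, 1.4, Inf, 3, 2, NA),
    pa_fdr = c(0.01, 0.01, 0.02, 0.2, 0.01, NA),
    psm_ratio = c(1.6, 2, 5, 2, 1.6, NA),
    psm_fdr = c(0.04, 0.04, 0, 0.01, 0.04, NA)
  )
  hits <- call_hits(res, q)
  f <- filter_funnel(hits)
  expect_identical(f$step[1], "all")
  expect_identical(f$n_remaining[1], 6L)
  ## manual tally: pa_ratio keeps {1,3,4,5}; +pa_fdr {1,3,5}; +psm_ratio {1,3,5};
  ## +psm_fdr {1,3,5}; +min_psm {1,3,5}
  expect_identical(f$n_remaining, c(6L, 4L, 3L, 3L, 3L, 3L))
  expect_true(all(diff(f$n_remaining) <= 0))

  ## empty order: single entry with the table size
  f0 <- filter_funnel(hits, order = character(0))
  expect_identical(nrow(f0), 1L)
  expect_identical(f0$n_remaining, 6L)

  ## any permutation of criteria gives the same final count
  flags <- attr(hits, "flags")
  for (i in 1:3) {
    perm_order <- sample(flags)
    expect_identical(
      dplyr::last(filter_funnel(hits, perm_order)$n_remaining),
      dplyr::last(f$n_remaining)
    )
  }
  expect_error(filter_funnel(hits, "pass_made_up"), "Unknown criterion")
})

test_that("tightening any threshold never increases the hit count", {
  sim <- simulate_pdl_experiment(sim_config(n_proteins = 150, seed = 77))
  res <- compare_groups(sim$quant,
    contrasts = "bait_vs_ctrl",
    perm = perm_config(n_permutations = 50, seed = 3)
  )
  withr::with_seed(7, {
    for (i in 1:8) {
      r1 <- runif(1, 1, 2.5)
      f1 <- runif(1, 0.01, 0.5)
      m1 <- runif(1, 0, 3)
      n_loose <- sum(call_hits(res, sim$quant, filter_thresholds(r1, f1, m1))$is_hit)
      n_tight <- sum(call_hits(
        res, sim$quant,
        filter_thresholds(r1 * 1.5, f1 / 2, m1 + 1)
      )$is_hit)
      expect_lte(n_tight, n_loose)
    }
  })
})

test_that("rank_hits is stable and direction-aware", {
  psm <- matrix(c(9L, 5L, 5L, 2L), 4, 6)
  q <- toy_quant(matrix(4, 4, 6), psm = psm, symbols = c("BAIT", "A", "B", "C"))
  res <- toy_results(
    q,
    pa_ratio = c(9, 3, 3, 2), pa_fdr = c(0.001, 0.01, 0.02, 0.04),
    psm_ratio = c(9, 3, 3, 2), psm_fdr = c(0.001, 0.01, 0.02, 0.04)
  )
  hits <- call_hits(res, q)
  expect_true(all(hits$is_hit))
  ranked <- rank_hits(hits, "avg_bait_psm")
  ## the bait protein itself (largest average PSM) ranks first
  expect_identical(ranked$symbol[1], "BAIT")
  ## equal keys keep input order (stable sort)
  expect_identical(ranked$symbol[2:3], c("A", "B"))
  ## FDR keys sort ascending; reversal under the opposite flag
  by_fdr <- rank_hits(hits, "pa_fdr")
  expect_identical(by_fdr$symbol[1], "BAIT")
  expect_identical(
    rank_hits(hits, "pa_fdr", decreasing = TRUE)$symbol,
    rev(by_fdr$symbol)
  )
  expect_error(rank_hits(hits, "nope"), "Unknown ranking key")
})
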