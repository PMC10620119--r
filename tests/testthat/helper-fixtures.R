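## Small in-code fixtures and independent oracles shared across tests.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A 2-group (bait vs ligase control), 3-vs-3 design: 20 possible label splits,
# small enough for exhaustive permutation enumeration.
design_3v3 <- function() {
  pdl_design(
    groups = c("BAIT", "LIGASE_CTRL"),
    n_experiments = 1, n_injections = 3
  )
}

# Build a pdl_quant from explicit matrices (psm defaults to round(pa)).
toy_quant <- function(pa, design = NULL, psm = NULL, symbols = NULL) {
  design <- design %||% design_3v3()
  n <- nrow(pa)
  acc <- sprintf("P%02d", seq_len(n))
  if (is.null(psm)) psm <- round(pa)
  dimnames(pa) <- dimnames(psm) <- list(acc, design$run_id)
  quant_table(
    proteins = tibble::tibble(
      accession = acc,
      symbol = symbols %||% sprintf("G%02d", seq_len(n))
    ),
    design = design, pa = pa, psm = psm
  )
}

# Random all-positive toy quant for the 3v3 design (no zeros, so every protein
# is testable and oracle bookkeeping stays simple).
random_3v3_quant <- function(n_proteins, seed) {
  withr::with_seed(seed, {
    pa <- matrix(2^rnorm(n_proteins * 6, 10, 1.5), n_proteins, 6)
    psm <- matrix(1L + rpois(n_proteins * 6, 5), n_proteins, 6)
  })
  toy_quant(pa, design = design_3v3(), psm = psm)
}

# Independent brute-force oracle for the exhaustive permutation FDR on fully
# observed data: plain loops, stats::t.test for every statistic, direct
# threshold counting, minimum-over-looser-thresholds monotonization.
oracle_perm_fdr_3v3 <- function(logvals, bait_cols, ctrl_cols) {
  n <- nrow(logvals)
  cols <- c(bait_cols, ctrl_cols)
  t_of_split <- function(b_idx) {
    vapply(seq_len(n), function(i) {
      unname(stats::t.test(
        logvals[i, b_idx], logvals[i, setdiff(cols, b_idx)],
        var.equal = TRUE, alternative = "greater"
      )$statistic)
    }, numeric(1))
  }
  t_obs <- t_of_split(bait_cols)
  splits <- combn(cols, length(bait_cols), simplify = FALSE)
  perm_t <- lapply(splits, t_of_split)
  raw <- vapply(seq_len(n), function(i) {
    fp <- mean(vapply(perm_t, function(ts) sum(ts >= t_obs[i]), numeric(1)))
    fp / sum(t_obs >= t_obs[i])
  }, numeric(1))
  fdr <- vapply(seq_len(n), function(i) {
    min(1, min(raw[t_obs <= t_obs[i]]))
  }, numeric(1))
  list(t = t_obs, fdr = fdr)
}

# Independent all-pairs shortest-path oracle (Floyd-Warshall).
oracle_shortest_paths <- function(vertices, edge_a, edge_b) {
  n <- length(vertices)
  d <- matrix(Inf, n, n, dimnames = list(vertices, vertices))
  diag(d) <- 0
  for (k in seq_along(edge_a)) {
    i <- match(edge_a[k], vertices)
    j <- match(edge_b[k], vertices)
    d[i, j] <- d[j, i] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Plain-loop silhouette of labels on a 2-D embedding (euclidean).
silhouette_mean <- function(xy, labels) {
  n <- nrow(xy)
  dmat <- as.matrix(dist(xy))
  s <- vapply(seq_len(n), function(i) {
    same <- labels == labels[i]
    a <- mean(dmat[i, same & seq_len(n) != i])
    b <- min(vapply(
      setdiff(unique(labels), labels[i]),
      function(g) mean(dmat[i, labels == g]), numeric(1)
    ))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Write a quant + design fixture pair to temp files; returns the two paths.
write_quant_fixture <- function(q, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  qp <- file.path(dir, "quant.tsv")
  dp <- file.path(dir, "design.csv")
  write_quant_table(q, qp, dp)
  c(quant = qp, design = dp)
}
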