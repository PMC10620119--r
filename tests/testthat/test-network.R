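test_that("annotate_hits counts the known-interactor overlap case-insensitively", {
  q <- toy_quant(matrix(4, 4, 6), psm = matrix(5L, 4, 6), symbols = c("Tak1", "TAB2", "Gsk3b", "Xyz"))
  res <- tidyr::expand_grid(
    metric = c("pa", "psm"),
    accession = q$proteins$accession
  ) |>
    dplyr::mutate(
      symbol = q$proteins$symbol[match(accession, q$proteins$accession)],
      contrast = "bait_vs_ctrl",
      mean_bait = 1, mean_ctrl = 1, ratio = 3, enrichment_pct = 75,
      t_stat = 3, df = 4, p_one_tailed = 0.01, fdr = 0.01,
      n_used_bait = 3, n_used_ctrl = 3, status = "ok"
    )
  class(res) <- c("pdl_comparison", class(res))
  hits <- call_hits(res, q)
  known <- interactor_set("ABI1", c("TAK1", "GSK3B", "NOTPRESENT"))
  ann <- annotate_hits(hits, known)
  expect_identical(sum(ann$is_known), 2L)
  expect_identical(attr(ann, "n_known_hits"), 2L)

  ## empty known set -> 0; all-known -> |hits|
  expect_identical(attr(annotate_hits(hits, interactor_set("ABI1", character(0))), "n_known_hits"), 0L)
  allk <- annotate_hits(hits, interactor_set("ABI1", q$proteins$symbol))
  expect_identical(attr(allk, "n_known_hits"), sum(hits$is_hit))

  ## alias map bridges nonstandard symbols
  ali <- annotate_hits(hits, interactor_set("ABI1", "MAP3K7"), alias = c(Tak1 = "MAP3K7"))
  expect_true(ali$is_known[ali$symbol == "Tak1"])
})

test_that("depths on a path graph and multi-path minimum are correct", {
  edges <- tibble::tibble(
    protein_a = c("F", "B", "C"),
    protein_b = c("B", "C", "D"),
    score = c(0.9, 0.8, 0.7)
  )
  d <- degree_stratify(edges, focal = "F", hits = c("B", "C", "D"))
  expect_identical(d$depth, c(1L, 2L, 3L))
  expect_identical(d$stratum, c("primary", "secondary", "tertiary"))
  expect_identical(tidy(d)$n, c(1L, 1L, 1L))

  ## a node with a length-2 and a length-3 path gets the minimum
  edges2 <- tibble::tibble(
    protein_a = c("F", "A", "F", "B", "C"),
    protein_b = c("A", "X", "B", "C", "X"),
    score = 0.9
  )
  d2 <- degree_stratify(edges2, "F", hits = "X")
  expect_identical(d2$depth, 2L)
})

test_that("depths equal an all-pairs shortest-path oracle on random graphs", {
  for (seed in c(2, 6)) {
    withr::with_seed(seed, {
      verts <- c("F", paste0("N", 1:11))
      ea <- sample(verts, 30, replace = TRUE)
      eb <- sample(verts, 30, replace = TRUE)
      keep <- ea != eb
      ea <- ea[keep]
      eb <- eb[keep]
    })
    edges <- tibble::tibble(protein_a = ea, protein_b = eb, score = NA_real_)
    hits <- paste0("N", 1:11)
    d <- degree_stratify(edges, "F", hits, max_depth = 11)
    oracle <- oracle_shortest_paths(verts, ea, eb)
    exp_depth <- oracle["F", hits]
    exp_depth[!is.finite(exp_depth)] <- NA
    expect_identical(d$depth, as.integer(exp_depth))
  }
})

test_that("depths are invariant to row order and duplicates; score filter monotone", {
  edges <- tibble::tibble(
    protein_a = c("F", "B", "C", "F"),
    protein_b = c("B", "C", "D", "B"), # duplicate F-B
    score = c(0.9, 0.45, 0.7, 0.5)
  )
  base <- degree_stratify(edges, "F", c("B", "C", "D"))
  shuf <- degree_stratify(edges[c(3, 1, 4, 2), ], "F", c("B", "C", "D"))
  expect_identical(base$depth, shuf$depth)

  ## tightening min_score never decreases any depth
  tight <- degree_stratify(edges, "F", c("B", "C", "D"), min_score = 0.6)
  cmp <- ifelse(is.na(tight$depth), Inf, tight$depth) >=
    ifelse(is.na(base$depth), Inf, base$depth)
  expect_true(all(cmp))
  ## the B-C edge (0.45) is gone at 0.6, so C and D are unreached
  expect_identical(tight$stratum, c("primary", "unreached", "unreached"))

  ## unscored edges survive any score filter
  mixed <- tibble::tibble(
    protein_a = c("F", "B"), protein_b = c("B", "C"),
    score = c(NA, 0.2)
  )
  keep_na <- degree_stratify(mixed, "F", c("B", "C"), min_score = 0.9)
  expect_identical(keep_na$depth, c(1L, NA_integer_))

  ## focal protein with no qualifying edges is flagged
  expect_warning(
    lonely <- degree_stratify(mixed[2, ], "F", c("B", "C")),
    "no edges"
  )
  expect_true(all(lonely$stratum == "unreached"))
})

test_that("interactor files and edge files round-trip through readers", {
  dir <- withr::local_tempdir()
  ip <- file.path(dir, "known.tsv")
  readr::write_tsv(tibble::tibble(
    focal = c("ABI1", "ABI1", "TAK1"),
    partner = c("WASF1", "Tak1", "TAB2"),
    sources = c("BioGRID;IntAct", "StringDB", "MINT")
  ), ip)
  ks <- read_interactor_set(ip, "ABI1")
  expect_identical(ks$partners, c("WASF1", "Tak1"))
  expect_identical(ks$sources[1], "BioGRID;IntAct")
  expect_error(read_interactor_set(ip, "NOPE"), "No rows")

  ep <- file.path(dir, "edges.tsv")
  readr::write_tsv(tibble::tibble(
    protein_a = c("A", "B", "C"), protein_b = c("B", "B", "D"),
    score = c(0.5, 0.9, NA)
  ), ep)
  el <- read_edge_list(ep)
  expect_identical(nrow(el), 2L) # self-loop dropped
  readr::write_tsv(tibble::tibble(protein_a = "A", protein_b = "B", score = 1.2), ep)
  expect_error(read_edge_list(ep), "\\[0, 1\\]")
})

test_that("DE-table filtering matches a manual tally and the up/down identity", {
  de <- tibble::tibble(
    symbol = paste0("G", 1:5),
    log2_fc = c(1.5, -2.0, 0.5, 1.0, -1.2),
    adj_p = c(0.01, 0.04, 0.001, 0.05, 0.2)
  )
  ## |FC| >= 2 (|log2| >= 1) and p <= 0.05: rows 1, 2, 4
  f <- filter_de_table(de)
  expect_identical(f$total, 3L)
  expect_identical(f$up, 2L)
  expect_identical(f$down, 1L)
  expect_identical(f$up + f$down, f$total)
  expect_identical(f$table$symbol, c("G1", "G2", "G4"))

  ## strict inequalities drop the boundary row (G4 has p = 0.05; G1/G2 pass > 2?)
  fs <- filter_de_table(de, strict = TRUE)
  expect_identical(fs$table$symbol, c("G1", "G2"))

  ## linear-scale fold changes
  del <- tibble::tibble(symbol = "X", fc = -2.5, padj = 0.01)
  fl <- filter_de_table(del, fc_col = "fc", adjp_col = "padj", fc_scale = "linear")
  expect_identical(fl$total, 1L)
  expect_identical(fl$down, 1L)

  ## empty table and missing columns
  f0 <- filter_de_table(de[0, ])
  expect_identical(c(f0$total, f0$up, f0$down), c(0L, 0L, 0L))
  expect_error(filter_de_table(de, fc_col = "missing"), "Missing column")
})

test_that("simulated DE tables are counted as configured", {
  de <- simulate_de_table(n_proteins = 1000, frac_changed = 0.1, frac_up = 0.77, seed = 3)
  f <- filter_de_table(de)
  expect_gt(f$total, 50)
  expect_gt(f$up / f$total, 0.6)
  expect_identical(f$up + f$down, f$total)
})
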