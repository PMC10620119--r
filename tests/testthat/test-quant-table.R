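test_that("read -> write -> read is the identity on all layers", {
  q <- random_3v3_quant(5, seed = 42)
  paths <- write_quant_fixture(q)
  q2 <- read_quant_table(paths["quant"], paths["design"])
  expect_equal(q2$pa, q$pa)
  expect_equal(q2$psm, q$psm)
  expect_equal(q2$proteins, q$proteins)
  expect_equal(q2$design, q$design)
  ## and once more through a second round trip
  paths2 <- write_quant_fixture(q2)
  q3 <- read_quant_table(paths2["quant"], paths2["design"])
  expect_equal(q3$pa, q$pa)
  expect_equal(q3$psm, q$psm)
})

test_that("a quant column without a design row is an error naming the column", {
  q <- random_3v3_quant(3, seed = 1)
  dir <- withr::local_tempdir()
  qp <- file.path(dir, "quant.tsv")
  dp <- file.path(dir, "design.csv")
  write_quant_table(q, qp, dp)
  d <- q$design[-2, ] # drop one run from the design
  readr::write_csv(d, dp)
  expect_error(
    read_quant_table(qp, dp),
    q$design$run_id[2],
    fixed = TRUE
  )
})

test_that("blank cells become zeros with the substitution count reported", {
  q <- random_3v3_quant(4, seed = 2)
  paths <- write_quant_fixture(q)
  lines <- readLines(paths["quant"])
  ## blank out three cells in the body (columns 3, 4 and 9 of rows 2 and 3)
  f <- strsplit(lines, "\t")
  f[[2]][3] <- ""
  f[[2]][9] <- ""
  f[[3]][4] <- ""
  writeLines(vapply(f, paste, character(1), collapse = "\t"), paths["quant"])
  expect_message(
    q2 <- read_quant_table(paths["quant"], paths["design"]),
    "3 blank"
  )
  expect_identical(attr(q2, "n_blank"), 3L)
  expect_equal(sum(q2$pa == 0) + sum(q2$psm == 0), 3)
})

test_that("unparseable cells, duplicate accessions and negatives are errors", {
  q <- random_3v3_quant(3, seed = 3)
  paths <- write_quant_fixture(q)
  lines <- readLines(paths["quant"])
  f <- strsplit(lines, "\t")
  f[[2]][3] <- "not_a_number"
  writeLines(vapply(f, paste, character(1), collapse = "\t"), paths["quant"])
  expect_error(read_quant_table(paths["quant"], paths["design"]), "Unparseable")

  expect_error(
    quant_table(
      proteins = tibble::tibble(accession = c("A", "A"), symbol = c("a", "a")),
      design = design_3v3(),
      pa = matrix(1, 2, 6), psm = matrix(1L, 2, 6)
    ),
    "Duplicate accession"
  )
  expect_error(
    quant_table(
      proteins = tibble::tibble(accession = c("A", "B"), symbol = c("a", "b")),
      design = design_3v3(),
      pa = matrix(-1, 2, 6), psm = matrix(1L, 2, 6)
    ),
    "negative"
  )
})

test_that("collate_experiments unions proteins with zero fill", {
  d1 <- pdl_design(groups = "BAIT", n_experiments = 1, n_injections = 2)
  d2 <- d1
  d2$run_id <- paste0(d2$run_id, "_x2")
  d2$experiment <- 2L # a second independent experiment
  mk <- function(acc, design, val) {
    quant_table(
      proteins = tibble::tibble(accession = acc, symbol = tolower(acc)),
      design = design,
      pa = matrix(val, length(acc), 2, dimnames = list(acc, design$run_id)),
      psm = matrix(1L, length(acc), 2, dimnames = list(acc, design$run_id))
    )
  }
  qa <- mk(c("A", "B"), d1, 2)
  qb <- mk(c("B", "C"), d2, 3)
  col <- collate_experiments(list(qa, qb))
  expect_setequal(col$proteins$accession, c("A", "B", "C"))
  expect_equal(unname(col$pa["A", d2$run_id]), c(0, 0))
  expect_equal(unname(col$pa["C", d1$run_id]), c(0, 0))
  expect_equal(unname(col$pa["B", ]), c(2, 2, 3, 3))
  ## single table is the identity
  one <- collate_experiments(list(qa))
  expect_equal(one$pa, qa$pa)
  expect_equal(one$design, qa$design)
  ## run_id collision is an error
  expect_error(collate_experiments(list(qa, qa)), "collision")
})

test_that("collating three disjoint tables matches a brute-force expected matrix", {
  designs <- lapply(1:3, function(k) {
    d <- pdl_design(groups = "BAIT", n_experiments = 1, n_injections = 2)
    d$run_id <- paste0(d$run_id, "_t", k)
    d$experiment <- k
    d
  })
  tabs <- lapply(1:3, function(k) {
    acc <- paste0("T", k, c("a", "b"))
    quant_table(
      proteins = tibble::tibble(accession = acc, symbol = acc),
      design = designs[[k]],
      pa = matrix(k * 10 + 1:4, 2, 2, dimnames = list(acc, designs[[k]]$run_id)),
      psm = matrix(k, 2, 2, dimnames = list(acc, designs[[k]]$run_id))
    )
  })
  col <- collate_experiments(tabs)
  expect_equal(dim(col$pa), c(6, 6))
  expected <- matrix(0, 6, 6,
    dimnames = list(col$proteins$accession, col$design$run_id)
  )
  for (t in tabs) expected[rownames(t$pa), colnames(t$pa)] <- t$pa
  expect_equal(col$pa, expected)
  ## total nonzero cell count is conserved
  expect_equal(
    sum(col$pa != 0),
    sum(vapply(tabs, function(t) sum(t$pa != 0), numeric(1)))
  )
  ## associativity of the protein union
  nested <- collate_experiments(list(collate_experiments(tabs[1:2]), tabs[[3]]))
  expect_setequal(nested$proteins$accession, col$proteins$accession)
  expect_equal(nested$pa[rownames(col$pa), colnames(col$pa)], col$pa)
})

test_that("detection is group-total PSM > 0 and satisfies inclusion-exclusion", {
  sim <- simulate_pdl_experiment(sim_config(n_proteins = 150, seed = 9))
  det <- summarize_detection(sim$quant)
  n_of <- function(s) det$n_detected[det$set == s]
  singles <- vapply(c("BAIT", "LIGASE_CTRL", "WILDTYPE"), n_of, integer(1))
  pairs <- vapply(
    c("BAIT+LIGASE_CTRL", "BAIT+WILDTYPE", "LIGASE_CTRL+WILDTYPE"),
    n_of, integer(1)
  )
  triple <- n_of("BAIT+LIGASE_CTRL+WILDTYPE")
  expect_equal(n_of("union"), sum(singles) - sum(pairs) + triple)

  ## an all-zero-PSM protein is detected nowhere but still in the table
  q <- sim$quant
  q$psm[1, ] <- 0L
  q$pa[1, ] <- 0
  det0 <- summarize_detection(q)
  in_bait <- rowSums(q$psm[, q$design$group == "BAIT", drop = FALSE]) > 0
  expect_false(in_bait[1])
  expect_equal(det0$n_detected[det0$set == "BAIT"], sum(in_bait))
  expect_equal(nrow(q$proteins), 150)
})
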