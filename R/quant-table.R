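#' Construct a PDL quantification table
#'
#' A `pdl_quant` bundles the two quantification layers of a proximity-dependent
#' labeling (PDL) MS experiment — chromatographic peak areas (PA) and peptide
#' spectral matches (PSM) — with the run design. Rows of both matrices are
#' proteins (named by accession), columns are MS runs (named by `run_id`).
#'
#' @param proteins Tibble with columns `accession` (unique) and `symbol`.
#' @param design Tibble with columns `run_id` (unique), `group` (one of
#'   `"BAIT"`, `"LIGASE_CTRL"`, `"WILDTYPE"`), `experiment` and `injection`
#'   (positive integers). Every (group, experiment, injection) combination
#'   must be unique.
#' @param pa Numeric matrix of nonnegative peak areas, proteins x runs.
#' @param psm Matrix of nonnegative integer spectral counts, proteins x runs.
#'
#' @return An object of class `pdl_quant`: a list with elements `proteins`,
#'   `design`, `pa`, `psm`.
#' @export
#' @examples
#' d <- pdl_design()
#' q <- quant_table(
#'   proteins = tibble::tibble(accession = c("P1", "P2"), symbol = c("A", "B")),
#'   design = d,
#'   pa = matrix(1, 2, 27, dimnames = list(c("P1", "P2"), d$run_id)),
#'   psm = matrix(1L, 2, 27, dimnames = list(c("P1", "P2"), d$run_id))
#' )
quant_table <- function(proteins, design, pa, psm) {
  proteins <- tibble::as_tibble(proteins)
  design <- as_pdl_design(design)
  pa <- as.matrix(pa)
  psm <- as.matrix(psm)
  if (anyDuplicated(proteins$accession)) {
    abort(paste0(
      "Duplicate accession(s): ",
      paste(unique(proteins$accession[duplicated(proteins$accession)]), collapse = ", ")
    ))
  }
  for (nm in c("pa", "psm")) {
    m <- get(nm)
    if (nrow(m) != nrow(proteins) || ncol(m) != nrow(design)) {
      abort(sprintf("`%s` must be %d proteins x %d runs", nm, nrow(proteins), nrow(design)))
    }
    if (anyNA(m)) abort(sprintf("`%s` contains NA; use 0 for non-detection", nm))
    if (any(m < 0)) abort(sprintf("`%s` contains negative values", nm))
  }
  if (any(psm != round(psm))) abort("`psm` must be integer-valued")
  dimnames(pa) <- dimnames(psm) <- list(proteins$accession, design$run_id)
  structure(
    list(proteins = proteins, design = design, pa = pa, psm = round(psm)),
    class = "pdl_quant"
  )
}

as_pdl_design <- function(design) {
  design <- tibble::as_tibble(design)
  need <- c("run_id", "group", "experiment", "injection")
  miss <- setdiff(need, names(design))
  if (length(miss)) abort(paste0("Design is missing column(s): ", paste(miss, collapse = ", ")))
  design$group <- as.character(design$group)
  bad <- setdiff(unique(design$group), PDL_GROUPS)
  if (length(bad)) {
    abort(paste0(
      "Unknown group label(s): ", paste(bad, collapse = ", "),
      " (expected ", paste(PDL_GROUPS, collapse = ", "), ")"
    ))
  }
  if (anyDuplicated(design$run_id)) abort("Design run_ids must be unique")
  key <- paste(design$group, design$experiment, design$injection)
  if (anyDuplicated(key)) abort("Each (group, experiment, injection) combination must be unique")
  design
}

#' @export
print.pdl_quant <- function(x, ...) {
  cat(sprintf(
    "<pdl_quant> %d proteins x %d runs (%s)\n",
    nrow(x$proteins), nrow(x$design),
    paste(sprintf("%s: %d", names(table(x$design$group)), table(x$design$group)), collapse = ", ")
  ))
  invisible(x)
}

#' Standard 27-run PDL design
#'
#' The canonical design of a three-arm PDL/MS study: bait, ligase-only control
#' and wildtype cell lines, each measured in three independent experiments with
#' three technical replicate injections (27 runs, n = 9 per group).
#'
#' @param groups Character vector of group labels.
#' @param n_experiments,n_injections Number of experiments and of injections
#'   per experiment.
#' @return Tibble with columns `run_id`, `group`, `experiment`, `injection`.
#' @export
pdl_design <- function(groups = PDL_GROUPS, n_experiments = 3, n_injections = 3) {
  d <- tidyr::expand_grid(
    group = groups,
    experiment = seq_len(n_experiments),
    injection = seq_len(n_injections)
  )
  d$run_id <- sprintf("%s_e%d_i%d", d$group, d$experiment, d$injection)
  d[, c("run_id", "group", "experiment", "injection")]
}

#' Read a quantification table and its run design
#'
#' Reads a wide-format protein quantification file with header
#' `accession, symbol, PA|<run_id>, ..., PSM|<run_id>, ...` plus a design file
#' with columns `run_id, group, experiment, injection`. Empty quantification
#' cells are treated as non-detections and become 0 (the count of substituted
#' blanks is reported via a message and the `"n_blank"` attribute);
#' unparseable non-empty cells are an error.
#'
#' @param path Path to the quant table (TSV or CSV by file extension).
#' @param design_path Path to the design table (CSV or TSV).
#' @return A [quant_table()] with attribute `n_blank`.
#' @export
read_quant_table <- function(path, design_path) {
  if (!file.exists(path)) abort(paste0("Quant file not found: ", path))
  if (!file.exists(design_path)) abort(paste0("Design file not found: ", design_path))
  design <- as_pdl_design(read_delim_auto(design_path))
  raw <- read_delim_auto(path, all_character = TRUE)
  if (!all(c("accession", "symbol") %in% names(raw))) {
    abort("Quant file must have `accession` and `symbol` columns")
  }
  qcols <- setdiff(names(raw), c("accession", "symbol"))
  parsed <- stringr::str_match(qcols, "^(PA|PSM)\\|(.+)$")
  if (anyNA(parsed[, 1])) {
    abort(paste0(
      "Unrecognized quant column(s): ",
      paste(qcols[is.na(parsed[, 1])], collapse = ", "),
      " (expected `PA|<run_id>` or `PSM|<run_id>`)"
    ))
  }
  missing_design <- setdiff(unique(parsed[, 3]), design$run_id)
  if (length(missing_design)) {
    abort(paste0(
      "Quant column(s) without a design row: ",
      paste(missing_design, collapse = ", ")
    ))
  }
  n_blank <- 0L
  layer <- function(tag) {
    keep <- parsed[, 2] == tag
    runs <- parsed[keep, 3]
    m <- matrix(0, nrow(raw), length(runs), dimnames = list(raw$accession, runs))
    for (j in seq_along(runs)) {
      v <- raw[[qcols[keep][j]]]
      blank <- is.na(v) | v == ""
      n_blank <<- n_blank + sum(blank)
      num <- suppressWarnings(as.numeric(v))
      bad <- !blank & is.na(num)
      if (any(bad)) {
        abort(sprintf(
          "Unparseable value(s) in column `%s`, e.g. \"%s\"",
          qcols[keep][j], v[bad][1]
        ))
      }
      num[blank] <- 0
      m[, j] <- num
    }
    m[, design$run_id[design$run_id %in% runs], drop = FALSE]
  }
  pa <- layer("PA")
  psm <- layer("PSM")
  if (!identical(colnames(pa), design$run_id) || !identical(colnames(psm), design$run_id)) {
    abort("Quant file must carry a PA and a PSM column for every design run")
  }
  if (n_blank > 0) inform(sprintf("Substituted 0 for %d blank quantification cell(s)", n_blank))
  q <- quant_table(raw[, c("accession", "symbol")], design, pa, psm)
  attr(q, "n_blank") <- n_blank
  q
}

read_delim_auto <- function(path, all_character = FALSE) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ct <- if (all_character) readr::cols(.default = readr::col_character()) else readr::cols()
  readr::read_delim(
    path,
    delim = delim, col_types = ct, comment = "#",
    progress = FALSE, show_col_types = FALSE
  )
}

#' Write a quantification table (and optionally its design) to disk
#'
#' Inverse of [read_quant_table()]: writes the wide `accession, symbol,
#' PA|<run>, PSM|<run>` layout.
#'
#' @param q A [quant_table()].
#' @param path Output path (TSV unless the extension is `.csv`).
#' @param design_path Optional path for the design table.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(q, path, design_path = NULL) {
  stopifnot(inherits(q, "pdl_quant"))
  pa <- tibble::as_tibble(q$pa)
  names(pa) <- paste0("PA|", q$design$run_id)
  psm <- tibble::as_tibble(q$psm)
  names(psm) <- paste0("PSM|", q$design$run_id)
  out <- dplyr::bind_cols(q$proteins, pa, psm)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(out, path, delim = delim)
  if (!is.null(design_path)) {
    readr::write_csv(q$design, design_path)
  }
  invisible(path)
}

#' Collate replicate PDL experiments into one quantification table
#'
#' Takes per-experiment quantification tables and unions their protein sets;
#' a protein absent from one table receives 0 (non-detection) in that table's
#' runs. Run order follows input order; `run_id`s must be disjoint.
#'
#' @param tables List of [quant_table()] objects.
#' @return A single [quant_table()].
#' @export
collate_experiments <- function(tables) {
  stopifnot(length(tables) >= 1, all(vapply(tables, inherits, logical(1), "pdl_quant")))
  all_runs <- unlist(lapply(tables, function(t) t$design$run_id))
  if (anyDuplicated(all_runs)) {
    abort(paste0(
      "run_id collision across tables: ",
      paste(unique(all_runs[duplicated(all_runs)]), collapse = ", ")
    ))
  }
  proteins <- dplyr::distinct(
    dplyr::bind_rows(lapply(tables, `[[`, "proteins")),
    .data$accession, .keep_all = TRUE
  )
  design <- dplyr::bind_rows(lapply(tables, `[[`, "design"))
  fill <- function(layer) {
    m <- matrix(0, nrow(proteins), length(all_runs),
      dimnames = list(proteins$accession, all_runs)
    )
    for (t in tables) m[rownames(t[[layer]]), colnames(t[[layer]])] <- t[[layer]]
    m
  }
  quant_table(proteins, design, fill("pa"), fill("psm"))
}

#' Per-group detection counts and overlaps
#'
#' A protein counts as detected in a group when its total PSM over that
#' group's runs exceeds zero (identification is spectrum-based, so detection
#' is defined on spectral counts, not peak areas). Overlap rows give the
#' counts of proteins detected in every group of the listed combination, and
#' `union` the number detected in at least one group.
#'
#' @param q A [quant_table()].
#' @return Tibble with columns `set` (group, `+`-joined combination, or
#'   `"union"`) and `n_detected`.
#' @export
summarize_detection <- function(q) {
  stopifnot(inherits(q, "pdl_quant"))
  groups <- unique(q$design$group)
  det <- vapply(
    groups,
    function(g) rowSums(q$psm[, q$design$group == g, drop = FALSE]) > 0,
    logical(nrow(q$proteins))
  )
  det <- matrix(det, ncol = length(groups), dimnames = list(NULL, groups))
  combos <- unlist(
    lapply(seq_along(groups), function(k) combn(groups, k, simplify = FALSE)),
    recursive = FALSE
  )
  tibble::tibble(
    set = c(vapply(combos, paste, character(1), collapse = "+"), "union"),
    n_detected = c(
      vapply(combos, function(cc) sum(rowSums(!det[, cc, drop = FALSE]) == 0), integer(1)),
      sum(rowSums(det) > 0)
    )
  )
}
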