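#' Curated interactor set
#'
#' A focal protein and its database-curated partner symbols, with per-partner
#' source tags (e.g. MINT, IntAct, BioGRID, StringDB). Symbols are compared
#' case-insensitively throughout the package, so murine-style (`Tab2`) and
#' human-style (`TAB2`) symbols interoperate.
#'
#' @param focal Focal protein symbol.
#' @param partners Character vector of partner symbols (the focal protein is
#'   removed if present).
#' @param sources Character vector of source tags, one per partner
#'   (semicolon-joined for multi-source evidence); recycled if length 1.
#' @return A list of class `interactor_set`.
#' @export
interactor_set <- function(focal, partners, sources = "curated") {
  stopifnot(is.character(focal), nchar(focal) > 0)
  partners <- as.character(partners)
  if (length(sources) == 1) sources <- rep(sources, length(partners))
  stopifnot(length(sources) == length(partners))
  keep <- !duplicated(toupper(partners)) & toupper(partners) != toupper(focal)
  structure(
    list(focal = focal, partners = partners[keep], sources = sources[keep]),
    class = "interactor_set"
  )
}

#' @export
print.interactor_set <- function(x, ...) {
  cat(sprintf(
    "<interactor_set> %s: %d curated partner(s)\n",
    x$focal, length(x$partners)
  ))
  invisible(x)
}

#' Read a curated interactor list
#'
#' TSV/CSV with columns `focal`, `partner`, `sources` (semicolon-joined tags;
#' optional). Files may hold several focal proteins; `focal` selects one.
#'
#' @param path File path.
#' @param focal Focal protein symbol to extract (default: the first in the
#'   file).
#' @return An [interactor_set()].
#' @export
read_interactor_set <- function(path, focal = NULL) {
  df <- read_delim_auto(path)
  if (!all(c("focal", "partner") %in% names(df))) {
    abort("Interactor list must have `focal` and `partner` columns")
  }
  focal <- focal %||% df$focal[1]
  df <- df[toupper(df$focal) == toupper(focal), ]
  if (!nrow(df)) abort(paste0("No rows for focal protein ", focal))
  interactor_set(
    focal = focal,
    partners = df$partner,
    sources = if ("sources" %in% names(df)) df$sources else "curated"
  )
}

#' Read an undirected interaction edge list
#'
#' TSV/CSV with columns `protein_a`, `protein_b` and optional `score`
#' (confidence in [0, 1]; rows from curated databases without a score keep
#' `NA` and survive any score filter). Self-loops are dropped.
#'
#' @param path File path.
#' @return Tibble with columns `protein_a`, `protein_b`, `score`.
#' @export
read_edge_list <- function(path) {
  df <- read_delim_auto(path)
  if (!all(c("protein_a", "protein_b") %in% names(df))) {
    abort("Edge list must have `protein_a` and `protein_b` columns")
  }
  if (!"score" %in% names(df)) df$score <- NA_real_
  bad <- !is.na(df$score) & (df$score < 0 | df$score > 1)
  if (any(bad)) abort("Edge scores must lie in [0, 1]")
  df <- df[toupper(df$protein_a) != toupper(df$protein_b), ]
  tibble::as_tibble(df[, c("protein_a", "protein_b", "score")])
}

normalize_symbols <- function(x, alias = NULL) {
  x <- toupper(x)
  if (!is.null(alias)) {
    names(alias) <- toupper(names(alias))
    hit <- match(x, names(alias))
    x[!is.na(hit)] <- toupper(alias[hit[!is.na(hit)]])
  }
  x
}

#' Annotate hits with known-interactor status
#'
#' Flags each protein whose symbol (case-insensitive, after optional alias
#' mapping) appears in a curated partner set, and reports the overlap between
#' hits and known interactors.
#'
#' @param hits A `pdl_hits` tibble from [call_hits()].
#' @param known An [interactor_set()].
#' @param alias Optional named character vector mapping nonstandard symbols to
#'   canonical ones.
#' @return The hit tibble with an `is_known` column; the number of known
#'   interactors among hits is attached as attribute `"n_known_hits"`.
#' @export
annotate_hits <- function(hits, known, alias = NULL) {
  partners <- normalize_symbols(known$partners, alias)
  hits$is_known <- normalize_symbols(hits$symbol, alias) %in% partners
  attr(hits, "n_known_hits") <- sum(hits$is_known & hits$is_hit)
  hits
}

#' Stratify hits by interaction-network depth from a focal protein
#'
#' Breadth-first shortest-path depth from the focal protein over the edges
#' with confidence score at least `min_score` (unscored, curated edges always
#' kept). Depth 1 = primary interactor, 2 = secondary, 3 = tertiary; depths
#' beyond `max_depth` (or disconnected proteins) are `"unreached"`. The focal
#' protein itself is excluded from the counts.
#'
#' @param edges Edge-list tibble (see [read_edge_list()]); duplicate edges and
#'   row order do not affect depths.
#' @param focal Focal protein symbol.
#' @param hits Character vector of hit symbols to stratify.
#' @param max_depth Maximum depth reported (default 3).
#' @param min_score Minimum interaction score (default 0.4, the conventional
#'   medium-confidence floor).
#' @param alias Optional symbol alias map.
#' @return Tibble of class `pdl_depths`: `symbol`, `depth` (integer or `NA`),
#'   `stratum` (`"primary"`, `"secondary"`, `"tertiary"`, depth labels beyond
#'   3, or `"unreached"`); per-stratum counts in attribute `"counts"`.
#' @export
#' @examples
#' edges <- tibble::tibble(
#'   protein_a = c("F", "B", "C"),
#'   protein_b = c("B", "C", "D"),
#'   score = c(0.9, 0.8, 0.7)
#' )
#' degree_stratify(edges, focal = "F", hits = c("B", "C", "D"))
degree_stratify <- function(edges, focal, hits, max_depth = 3, min_score = 0.4, alias = NULL) {
  stopifnot(min_score >= 0, min_score <= 1, max_depth >= 1)
  if (!all(c("protein_a", "protein_b") %in% names(edges))) {
    abort("Edge list must have `protein_a` and `protein_b` columns")
  }
  if (!"score" %in% names(edges)) edges$score <- NA_real_
  keep <- is.na(edges$score) | edges$score >= min_score
  ea <- normalize_symbols(edges$protein_a[keep], alias)
  eb <- normalize_symbols(edges$protein_b[keep], alias)
  self <- ea == eb
  ea <- ea[!self]
  eb <- eb[!self]
  focal_n <- normalize_symbols(focal, alias)
  hits_n <- normalize_symbols(hits, alias)

  verts <- unique(c(focal_n, ea, eb))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ea, to = eb),
    directed = FALSE,
    vertices = verts
  )
  if (!focal_n %in% ea && !focal_n %in% eb) {
    warn(sprintf("Focal protein %s has no edges at min_score >= %.2f", focal, min_score))
  }
  d <- igraph::distances(g, v = focal_n, weights = NA)[1, ]
  depth <- unname(d[match(hits_n, names(d))])
  depth[!is.finite(depth) | depth > max_depth | depth == 0] <- NA
  labels <- c("primary", "secondary", "tertiary")
  stratum <- ifelse(
    is.na(depth), "unreached",
    ifelse(depth <= 3, labels[pmax(depth, 1)], paste0("depth", depth))
  )
  out <- tibble::tibble(
    symbol = hits,
    depth = as.integer(depth),
    stratum = stratum
  )
  out <- out[toupper(out$symbol) != toupper(focal_n), ]
  counts <- dplyr::count(out, .data$stratum, name = "n")
  class(out) <- c("pdl_depths", class(out))
  attr(out, "counts") <- counts
  attr(out, "focal") <- focal
  out
}

#' Filter a differential-expression table by fold change and adjusted p
#'
#' Generic significance filter for whole-proteome differential-abundance
#' results: keeps rows with absolute fold change at least `fc_min` and
#' adjusted p-value at most `adjp_max` (non-strict comparisons by default;
#' `strict = TRUE` uses `>` / `<`), and counts up- and down-regulated
#' survivors.
#'
#' @param de Tibble with a signed fold-change column and an adjusted-p column.
#' @param fc_col,adjp_col Column names (defaults `"log2_fc"`, `"adj_p"`).
#' @param fc_min Minimum fold change on the *linear* scale (default 2).
#' @param adjp_max Maximum adjusted p-value (default 0.05).
#' @param fc_scale `"log2"` (column holds signed log2 FC) or `"linear"`
#'   (signed linear ratio).
#' @param strict Use strict inequalities.
#' @return List of class `pdl_de_filter`: `table` (significant rows),
#'   `total`, `up`, `down`.
#' @export
filter_de_table <- function(de, fc_col = "log2_fc", adjp_col = "adj_p",
                            fc_min = 2, adjp_max = 0.05,
                            fc_scale = c("log2", "linear"), strict = FALSE) {
  fc_scale <- match.arg(fc_scale)
  miss <- setdiff(c(fc_col, adjp_col), names(de))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  fc <- de[[fc_col]]
  mag <- if (fc_scale == "log2") 2^abs(fc) else abs(fc)
  p <- de[[adjp_col]]
  sig <- if (strict) mag > fc_min & p < adjp_max else mag >= fc_min & p <= adjp_max
  sig <- !is.na(sig) & sig
  tab <- de[sig, ]
  structure(
    list(
      table = tab,
      total = sum(sig),
      up = sum(sig & fc > 0),
      down = sum(sig & fc < 0)
    ),
    class = "pdl_de_filter"
  )
}

#' @export
print.pdl_de_filter <- function(x, ...) {
  cat(sprintf(
    "<pdl_de_filter> %d significant (%d up, %d down)\n",
    x$total, x$up, x$down
  ))
  invisible(x)
}
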