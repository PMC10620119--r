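#' Pipeline configuration
#'
#' Assembles everything [run_pipeline()] needs: either paths to a quant table
#' and design file, or a [sim_config()] to generate data; hit-calling
#' thresholds; permutation settings; calibration grid; and the annotation
#' inputs (known-interactor list and edge list, as paths or in-memory
#' objects).
#'
#' @param quant_path,design_path Paths to an on-disk quantification/design
#'   table pair, or `NULL` to simulate.
#' @param sim A [sim_config()] used when no quant path is given.
#' @param thresholds A [filter_thresholds()].
#' @param perm A [perm_config()].
#' @param focal Focal protein symbol for annotation stages.
#' @param grid Calibration cutoff grid.
#' @param known Optional [interactor_set()] or path to one; `NULL` simulates
#'   an annotation set from ground truth (simulated data only).
#' @param edges Optional edge-list tibble or path; `NULL` simulates one
#'   (simulated data only).
#' @param min_score,max_depth Edge-score floor and depth cap for
#'   stratification.
#' @param out_dir Output directory for stage TSVs and the report.
#' @param seed Master seed; stage seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(quant_path = NULL, design_path = NULL,
                            sim = sim_config(),
                            thresholds = filter_thresholds(),
                            perm = perm_config(),
                            focal = "BAIT",
                            grid = calibration_grid(),
                            known = NULL,
                            edges = NULL,
                            min_score = 0.4,
                            max_depth = 3,
                            out_dir = tempfile("pdl_run_"),
                            seed = 1L) {
  structure(
    list(
      quant_path = quant_path, design_path = design_path,
      sim = sim, thresholds = thresholds, perm = perm,
      focal = focal, grid = grid, known = known, edges = edges,
      min_score = min_score, max_depth = max_depth,
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Validate a pipeline configuration
#'
#' @param cfg A [pipeline_config()].
#' @return Character vector of problems, one per issue, each naming the field;
#'   empty when the configuration is runnable.
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  if (!is.null(cfg$quant_path)) {
    if (!file.exists(cfg$quant_path)) note(paste0("quant_path: file not found: ", cfg$quant_path))
    if (is.null(cfg$design_path)) {
      note("design_path: required when quant_path is set")
    } else if (!file.exists(cfg$design_path)) {
      note(paste0("design_path: file not found: ", cfg$design_path))
    }
  } else {
    ok <- tryCatch(
      {
        validate_sim_config(cfg$sim)
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) note("sim: invalid simulation configuration")
  }
  th <- cfg$thresholds
  if (!inherits(th, "filter_thresholds")) {
    note("thresholds: not a filter_thresholds object")
  } else {
    if (!is.numeric(th$min_ratio) || th$min_ratio <= 0) note("thresholds$min_ratio: must be > 0")
    if (!is.numeric(th$max_fdr) || th$max_fdr <= 0 || th$max_fdr > 1) {
      note("thresholds$max_fdr: must be in (0, 1]")
    }
    if (th$min_avg_psm_per_injection < 0) note("thresholds$min_avg_psm_per_injection: must be >= 0")
  }
  if (!length(cfg$grid) || any(cfg$grid <= 0) || is.unsorted(cfg$grid, strictly = TRUE)) {
    note("grid: must be strictly increasing and positive")
  }
  if (cfg$min_score < 0 || cfg$min_score > 1) note("min_score: must be in [0, 1]")
  if (is.character(cfg$known) && !file.exists(cfg$known)) {
    note(paste0("known: file not found: ", cfg$known))
  }
  if (is.character(cfg$edges) && !file.exists(cfg$edges)) {
    note(paste0("edges: file not found: ", cfg$edges))
  }
  problems
}

provenance_header <- function(cfg, stage) {
  c(
    sprintf("# proxhits %s | stage=%s", as.character(packageVersion("proxhits")), stage),
    sprintf("# seed=%d", cfg$seed),
    sprintf(
      "# thresholds: min_ratio=%g max_fdr=%g min_avg_psm=%g require_wt=%s",
      cfg$thresholds$min_ratio, cfg$thresholds$max_fdr,
      cfg$thresholds$min_avg_psm_per_injection, cfg$thresholds$require_wt_contrast
    ),
    sprintf(
      "# permutations: n=%d exhaustive_limit=%d s0=%g",
      cfg$perm$n_permutations, cfg$perm$exhaustive_limit, cfg$perm$s0
    )
  )
}

#' Write a result table as TSV with a provenance comment header
#'
#' @param x Data frame.
#' @param path Output path.
#' @param header Character vector of `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path File path.
#' @return Tibble (comment lines skipped).
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, comment = "#", progress = FALSE, show_col_types = FALSE)
}

#' Run the full PDL hit-calling pipeline
#'
#' Orchestrates simulate/read -> enrichment statistics -> hit filtering ->
#' threshold calibration -> annotation and depth stratification, writing every
#' stage output as a TSV with a provenance header plus a human-readable
#' `report.txt` into `cfg$out_dir`. With a fixed seed the run is fully
#' deterministic.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results (`quant`,
#'   `truth`, `results`, `hits`, `funnel`, `calibration`, `detection`,
#'   `depths`, `known`, plus `out_dir`).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  problems <- validate_config(cfg)
  if (length(problems)) {
    abort(paste0(
      "Invalid pipeline configuration:\n",
      paste0("- ", problems, collapse = "\n")
    ))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  truth <- NULL
  if (is.null(cfg$quant_path)) {
    sim_cfg <- cfg$sim
    sim_cfg$seed <- cfg$seed
    sim <- stage("simulate", simulate_pdl_experiment(sim_cfg))
    quant <- sim$quant
    truth <- sim$truth
    write_quant_table(
      quant,
      file.path(cfg$out_dir, "quant.tsv"),
      file.path(cfg$out_dir, "design.csv")
    )
    write_result_table(truth, file.path(cfg$out_dir, "truth.tsv"), provenance_header(cfg, "simulate"))
  } else {
    quant <- stage("read", read_quant_table(cfg$quant_path, cfg$design_path))
  }

  known <- cfg$known
  if (is.character(known)) known <- stage("read_known", read_interactor_set(known, cfg$focal))
  if (is.null(known) && !is.null(truth)) {
    known <- simulate_annotation(truth, focal = cfg$focal, seed = cfg$seed + 1L)
  }
  edges <- cfg$edges
  if (is.character(edges)) edges <- stage("read_edges", read_edge_list(edges))
  if (is.null(edges) && !is.null(truth)) {
    edges <- simulate_edge_list(truth, focal = cfg$focal, seed = cfg$seed + 2L)
  }

  perm <- cfg$perm
  perm$seed <- cfg$seed + 3L
  contrasts <- c("bait_vs_ctrl", if (cfg$thresholds$require_wt_contrast) "bait_vs_wt")
  results <- stage("test", compare_groups(quant, contrasts = contrasts, perm = perm))
  write_result_table(results, file.path(cfg$out_dir, "results.tsv"), provenance_header(cfg, "test"))

  detection <- stage("detect", summarize_detection(quant))
  write_result_table(detection, file.path(cfg$out_dir, "detection.tsv"), provenance_header(cfg, "detect"))

  hits <- stage("filter", call_hits(results, quant, cfg$thresholds))
  if (!is.null(known)) hits <- annotate_hits(hits, known)
  funnel <- filter_funnel(hits)
  write_result_table(hits, file.path(cfg$out_dir, "hits.tsv"), provenance_header(cfg, "filter"))
  write_result_table(funnel, file.path(cfg$out_dir, "funnel.tsv"), provenance_header(cfg, "filter"))

  calibration <- NULL
  if (!is.null(known)) {
    calibration <- stage(
      "calibrate",
      known_recovery_curve(results, known, grid = cfg$grid)
    )
    write_result_table(
      calibration$curve,
      file.path(cfg$out_dir, "calibration.tsv"),
      c(
        provenance_header(cfg, "calibrate"),
        sprintf(
          "# slope=%.6g intercept=%.6g suggested_cutoff=%.6g",
          calibration$slope, calibration$intercept, calibration$suggested_cutoff
        )
      )
    )
  }

  depths <- NULL
  if (!is.null(edges)) {
    hit_syms <- hits$symbol[hits$is_hit]
    depths <- stage(
      "annotate",
      degree_stratify(edges, cfg$focal, hit_syms,
        max_depth = cfg$max_depth, min_score = cfg$min_score
      )
    )
    write_result_table(depths, file.path(cfg$out_dir, "depths.tsv"), provenance_header(cfg, "annotate"))
  }

  report <- c(
    provenance_header(cfg, "report"),
    "",
    sprintf("Proteins quantified: %d", nrow(quant$proteins)),
    sprintf(
      "Detection (PSM > 0): %s",
      paste(sprintf("%s=%d", detection$set, detection$n_detected), collapse = ", ")
    ),
    "",
    "Filter funnel:",
    sprintf("  %-22s %d", funnel$step, funnel$n_remaining),
    "",
    sprintf("Hits: %d", sum(hits$is_hit)),
    if (!is.null(known)) {
      sprintf("Known %s interactors among hits: %d", cfg$focal, attr(hits, "n_known_hits"))
    },
    if (!is.null(calibration)) {
      sprintf(
        "Calibration (%s): suggested ratio cutoff %.3g",
        calibration$metric, calibration$suggested_cutoff
      )
    },
    if (!is.null(depths)) {
      cc <- attr(depths, "counts")
      sprintf(
        "Depth strata around %s: %s", cfg$focal,
        paste(sprintf("%s=%d", cc$stratum, cc$n), collapse = ", ")
      )
    }
  )
  writeLines(report, file.path(cfg$out_dir, "report.txt"))

  invisible(list(
    quant = quant, truth = truth, results = results, hits = hits,
    funnel = funnel, calibration = calibration, detection = detection,
    depths = depths, known = known, out_dir = cfg$out_dir
  ))
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a plain-text configuration with optional sections `sim`,
#' `thresholds`, `perm` and top-level keys matching [pipeline_config()]
#' arguments; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$sim)) args$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$thresholds)) args$thresholds <- do.call(filter_thresholds, y$thresholds)
  if (!is.null(y$perm)) args$perm <- do.call(perm_config, y$perm)
  scalar_keys <- c(
    "quant_path", "design_path", "focal", "grid", "known", "edges",
    "min_score", "max_depth", "out_dir", "seed"
  )
  extra <- setdiff(names(y), c(scalar_keys, "sim", "thresholds", "perm"))
  if (length(extra)) abort(paste0("Unknown config key(s): ", paste(extra, collapse = ", ")))
  args <- c(args, y[intersect(names(y), scalar_keys)])
  do.call(pipeline_config, args)
}
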