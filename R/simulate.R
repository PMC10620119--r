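#' Simulation configuration for a synthetic PDL/MS experiment
#'
#' Parameters of the generative model used by [simulate_pdl_experiment()].
#' The defaults describe a typical three-arm TurboID experiment: a bait line,
#' a ligase-only control with substantial nonspecific biotinylation, and a
#' wildtype line with negligible labeling, each measured as 3 experiments x
#' 3 injections (27 runs).
#'
#' The model, on the log2 peak-area scale: each protein draws a baseline
#' abundance `N(background_mu, background_sigma)`; every (protein, experiment)
#' pair draws a shared batch effect `N(0, experiment_sd)`; every cell adds
#' injection noise `N(0, injection_sd)`. True interactors add a protein-level
#' enrichment `N(log2_effect_mean, log2_effect_sd)` in bait runs only.
#' Wildtype intensities are divided by `wildtype_attenuation`. Control-run
#' values of true interactors are zeroed (structural zeros — the protein is
#' simply not labeled without the bait) with probability `dropout_prob_ctrl`.
#' PSM counts are Poisson with mean proportional to the linear peak area:
#' `psm_per_intensity` expected counts at log2 intensity `psm_ref_log2`,
#' scaling linearly with intensity, and 0 wherever PA is 0.
#'
#' @param n_proteins Number of simulated proteins.
#' @param frac_true_interactors Fraction of proteins that are genuine proximal
#'   interactors of the bait.
#' @param log2_effect_mean,log2_effect_sd Bait-vs-control enrichment of true
#'   interactors on the log2 scale.
#' @param background_mu,background_sigma Mean and SD of baseline log2 peak
#'   area (log-normal PA).
#' @param wildtype_attenuation Divisor (>= 1) applied to wildtype intensities;
#'   large values mean negligible labeling without a biotin ligase.
#' @param dropout_prob_ctrl Structural-zero probability for true interactors
#'   in ligase-control runs.
#' @param psm_per_intensity Expected PSM per injection for a protein at the
#'   reference intensity.
#' @param psm_ref_log2 Reference log2 peak area at which the expected PSM
#'   equals `psm_per_intensity`.
#' @param experiment_sd,injection_sd Nested noise SDs (log2 scale).
#' @param interactor_min_z Detectability floor for spiked true interactors:
#'   their baseline abundance is truncated below at
#'   `background_mu + interactor_min_z * background_sigma`. A protein the MS
#'   cannot sample at a few spectra per run cannot be established (or curated)
#'   as an interactor, so true interactors are drawn from the detectable part
#'   of the abundance distribution. Set to `-Inf` to disable.
#' @param seed Integer seed; identical seeds give bit-identical simulations.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 2000,
                       frac_true_interactors = 0.10,
                       log2_effect_mean = 2.0,
                       log2_effect_sd = 0.5,
                       background_mu = 20,
                       background_sigma = 3,
                       wildtype_attenuation = 50,
                       dropout_prob_ctrl = 0.15,
                       psm_per_intensity = 6,
                       psm_ref_log2 = 20,
                       experiment_sd = 0.5,
                       injection_sd = 0.3,
                       interactor_min_z = -0.5,
                       seed = 1L) {
  cfg <- list(
    n_proteins = n_proteins,
    frac_true_interactors = frac_true_interactors,
    log2_effect_mean = log2_effect_mean,
    log2_effect_sd = log2_effect_sd,
    background_mu = background_mu,
    background_sigma = background_sigma,
    wildtype_attenuation = wildtype_attenuation,
    dropout_prob_ctrl = dropout_prob_ctrl,
    psm_per_intensity = psm_per_intensity,
    psm_ref_log2 = psm_ref_log2,
    experiment_sd = experiment_sd,
    injection_sd = injection_sd,
    interactor_min_z = interactor_min_z,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_proteins >= 1,
    cfg$frac_true_interactors >= 0, cfg$frac_true_interactors <= 1,
    cfg$dropout_prob_ctrl >= 0, cfg$dropout_prob_ctrl <= 1,
    cfg$log2_effect_sd >= 0, cfg$background_sigma >= 0,
    cfg$experiment_sd >= 0, cfg$injection_sd >= 0,
    cfg$wildtype_attenuation >= 1,
    cfg$psm_per_intensity > 0
  )
  invisible(cfg)
}

#' Simulate a proximity-labeling experiment with known ground truth
#'
#' Generates a 27-run [quant_table()] (3 groups x 3 experiments x 3
#' injections) under the model described in [sim_config()], together with the
#' per-protein ground truth needed to score the downstream pipeline.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `quant` (a [quant_table()]) and `truth`
#'   (tibble: `accession`, `symbol`, `is_true_interactor`, `log2_effect`),
#'   carrying `cfg` as an attribute.
#' @export
#' @examples
#' sim <- simulate_pdl_experiment(sim_config(n_proteins = 50, seed = 7))
#' sum(sim$truth$is_true_interactor)
simulate_pdl_experiment <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  design <- pdl_design()
  withr::with_seed(cfg$seed, {
    n <- cfg$n_proteins
    acc <- sprintf("SIMP%04d", seq_len(n))
    sym <- sprintf("Simg%04d", seq_len(n))
    n_true <- round(cfg$frac_true_interactors * n)
    is_true <- c(rep(TRUE, n_true), rep(FALSE, n - n_true))
    effect <- ifelse(is_true, rnorm(n, cfg$log2_effect_mean, cfg$log2_effect_sd), 0)

    baseline <- rnorm(n, cfg$background_mu, cfg$background_sigma)
    if (n_true > 0 && is.finite(cfg$interactor_min_z)) {
      ## true interactors come from the detectable part of the proteome:
      ## redraw their baseline from the normal truncated at mu + z_min * sigma
      pz <- stats::pnorm(cfg$interactor_min_z)
      u <- stats::runif(n_true, pz, 1)
      baseline[seq_len(n_true)] <- cfg$background_mu +
        cfg$background_sigma * stats::qnorm(u)
    }
    n_runs <- nrow(design)
    ## shared (protein x experiment) batch effect, then per-cell injection noise
    batch <- matrix(rnorm(n * 3, 0, cfg$experiment_sd), n, 3)
    log2pa <- baseline +
      batch[, design$experiment] +
      matrix(rnorm(n * n_runs, 0, cfg$injection_sd), n, n_runs)
    bait_cols <- design$group == "BAIT"
    ctrl_cols <- design$group == "LIGASE_CTRL"
    wt_cols <- design$group == "WILDTYPE"
    log2pa[, bait_cols] <- log2pa[, bait_cols] + effect
    log2pa[, wt_cols] <- log2pa[, wt_cols] - log2(cfg$wildtype_attenuation)

    pa <- 2^log2pa
    if (n_true > 0 && cfg$dropout_prob_ctrl > 0) {
      drop <- matrix(
        stats::runif(n_true * sum(ctrl_cols)) < cfg$dropout_prob_ctrl,
        n_true, sum(ctrl_cols)
      )
      sub <- pa[seq_len(n_true), ctrl_cols, drop = FALSE]
      sub[drop] <- 0
      pa[seq_len(n_true), ctrl_cols] <- sub
    }
    lambda <- cfg$psm_per_intensity * pa / 2^cfg$psm_ref_log2
    psm <- matrix(rpois(n * n_runs, pmin(lambda, 1e6)), n, n_runs)
    psm[pa == 0] <- 0L

    dimnames(pa) <- dimnames(psm) <- list(acc, design$run_id)
    quant <- quant_table(tibble::tibble(accession = acc, symbol = sym), design, pa, psm)
    truth <- tibble::tibble(
      accession = acc, symbol = sym,
      is_true_interactor = is_true, log2_effect = effect
    )
  })
  out <- list(quant = quant, truth = truth)
  attr(out, "cfg") <- cfg
  out
}

#' Simulate a curated known-interactor set from ground truth
#'
#' Emulates a database-curated partner list for the bait: a random `coverage`
#' fraction of the true interactors is "published", and `contamination` x the
#' resulting set size of random non-interactors is added (curation errors /
#' context-irrelevant interactions).
#'
#' @param truth Truth tibble from [simulate_pdl_experiment()].
#' @param coverage Fraction of true interactors present in the curated set.
#' @param contamination Fraction of the covered set size added from
#'   non-interactors.
#' @param focal Symbol of the focal (bait) protein.
#' @param seed Integer seed.
#' @return An [interactor_set()].
#' @export
simulate_annotation <- function(truth, coverage = 0.6, contamination = 0.2,
                                focal = "BAIT", seed = 1L) {
  stopifnot(coverage >= 0, coverage <= 1, contamination >= 0, contamination <= 1)
  withr::with_seed(as.integer(seed), {
    true_sym <- truth$symbol[truth$is_true_interactor]
    other_sym <- truth$symbol[!truth$is_true_interactor]
    n_cov <- round(coverage * length(true_sym))
    covered <- if (n_cov > 0) sample(true_sym, n_cov) else character(0)
    n_con <- round(contamination * length(covered))
    contam <- if (n_con > 0) sample(other_sym, min(n_con, length(other_sym))) else character(0)
    partners <- c(covered, contam)
  })
  interactor_set(
    focal = focal,
    partners = partners,
    sources = rep("StringDB", length(partners))
  )
}

#' Simulate a scored interaction edge list around a focal protein
#'
#' Builds an undirected StringDB-like edge list in which a configurable
#' fraction of true interactors are direct (depth-1) partners of the focal
#' protein, further true interactors chain off those at depths 2 and 3, and
#' random background edges connect non-interactors. Edge confidence scores
#' are drawn uniformly on [0.4, 1).
#'
#' @param truth Truth tibble from [simulate_pdl_experiment()].
#' @param focal Focal protein symbol (added as a node).
#' @param frac_primary Fraction of true interactors wired as direct partners.
#' @param n_background Number of random background edges among non-interactors.
#' @param seed Integer seed.
#' @return Tibble with columns `protein_a`, `protein_b`, `score`.
#' @export
simulate_edge_list <- function(truth, focal = "BAIT", frac_primary = 0.2,
                               n_background = 200, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    true_sym <- truth$symbol[truth$is_true_interactor]
    other_sym <- truth$symbol[!truth$is_true_interactor]
    edges <- list()
    if (length(true_sym) >= 1) {
      n1 <- max(1, round(frac_primary * length(true_sym)))
      depth1 <- sample(true_sym, n1)
      edges[[1]] <- tibble::tibble(protein_a = focal, protein_b = depth1)
      rest <- setdiff(true_sym, depth1)
      prev <- depth1
      for (d in 2:3) {
        if (!length(rest)) break
        take <- sample(rest, min(length(rest), n1 * 2))
        edges[[d]] <- tibble::tibble(
          protein_a = sample(prev, length(take), replace = TRUE),
          protein_b = take
        )
        rest <- setdiff(rest, take)
        prev <- take
      }
    }
    if (n_background > 0 && length(other_sym) >= 2) {
      edges[[length(edges) + 1]] <- tibble::tibble(
        protein_a = sample(other_sym, n_background, replace = TRUE),
        protein_b = sample(other_sym, n_background, replace = TRUE)
      )
    }
    out <- dplyr::bind_rows(edges)
    out <- out[out$protein_a != out$protein_b, ]
    out$score <- round(stats::runif(nrow(out), 0.4, 0.999), 3)
  })
  out
}

#' Simulate a differential-expression result table
#'
#' Emulates a whole-proteome differential-abundance result (log2 fold change
#' plus FDR-adjusted p-value per protein) of the kind produced by a
#' moderated-t workflow, for exercising [filter_de_table()]. A fraction of
#' proteins receive a genuine shift; adjusted p-values are generated so that
#' shifted proteins are mostly significant.
#'
#' @param n_proteins Number of rows.
#' @param frac_changed Fraction of proteins with a genuine >= 2-fold shift.
#' @param frac_up Fraction of changed proteins shifted upward.
#' @param seed Integer seed.
#' @return Tibble with columns `symbol`, `log2_fc`, `adj_p`.
#' @export
simulate_de_table <- function(n_proteins = 1000, frac_changed = 0.1,
                              frac_up = 0.77, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    n_chg <- round(frac_changed * n_proteins)
    n_up <- round(frac_up * n_chg)
    changed <- c(rep(TRUE, n_chg), rep(FALSE, n_proteins - n_chg))
    sign <- c(rep(1, n_up), rep(-1, n_chg - n_up), rep(0, n_proteins - n_chg))
    lfc <- ifelse(
      changed,
      sign * (1 + stats::rexp(n_proteins, 2)),
      rnorm(n_proteins, 0, 0.3)
    )
    adj_p <- ifelse(
      changed,
      stats::rbeta(n_proteins, 0.5, 40),
      stats::rbeta(n_proteins, 2, 3)
    )
    tibble::tibble(
      symbol = sprintf("Deg%04d", seq_len(n_proteins)),
      log2_fc = lfc,
      adj_p = pmin(adj_p, 1)
    )
  })
}
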