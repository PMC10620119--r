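---
title: "Calling proximal interactors from dual-metric PDL/MS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling proximal interactors from dual-metric PDL/MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxhits)
```

## The problem and the data model

Proximity-dependent labeling (PDL) with a promiscuous biotin ligase such as
TurboID tags proteins near a bait in living cells; streptavidin capture and
label-free LC–MS/MS then quantify what was tagged. The ligase alone
biotinylates thousands of proteins, so the inferential task is to find the
proteins whose labeling is *bait-dependent*, against three arms:

* **bait** — ligase fused to the protein of interest,
* **ligase control** — ligase alone, carrying the full nonspecific background,
* **wildtype** — no ligase, essentially no labeling.

Each arm is measured in independent experiments with technical replicate
injections (the canonical design here is 3 × 3 × 3 = 27 runs, n = 9 per arm).
Every protein carries two quantities per run: the chromatographic **peak
area** (PA, a continuous intensity) and the **peptide spectral match** count
(PSM, a discrete sampling-based abundance proxy). The two respond differently
to protein size, digestibility and ionization, so `proxhits` requires
agreement between them before calling a hit — a deliberately conservative
conjunction.

## Enrichment statistics

`compare_groups()` computes, per protein, metric and contrast:

* **Log-scale test.** Values are log2-transformed; zeros are structural
  non-detections, not small measurements, and become missing rather than
  `-Inf`. A one-tailed pooled-variance Student's *t* is computed on the
  non-missing values, with p = P(T~df~ ≥ t) for the alternative that the bait
  mean exceeds the control mean. Pooled variance (rather than Welch) matches
  the classical two-sample test used by the standard proteomics platforms for
  this design. A protein with fewer than two non-missing values in either
  group is flagged `untestable` — it is kept in the table (its ratio and
  enrichment percentage remain informative) but fails FDR-based criteria.
  Zero-pooled-variance cases are flagged `degenerate` with the convention
  p = 0.5 / 0 / 1 for equal / larger / smaller bait means.

* **Permutation FDR.** For each observed statistic used as a threshold,
  FDR(t) is the mean number of permutation statistics at or above t, divided
  by the number of observed statistics at or above t. Group labels of the
  contrast's runs are permuted; when the number of distinct label splits is
  at most `exhaustive_limit` (default 20000) all splits are enumerated and
  the estimate is deterministic, otherwise `n_permutations` (default 250)
  random splits are drawn under a seed. The default limit deliberately leaves
  the 9-vs-9 design (48620 splits) in random-permutation mode; raising the
  limit buys exact enumeration at ~200× the cost. Raw estimates are
  monotonized (a running minimum from the loosest threshold upward), so FDR
  never increases with the statistic, and clipped to [0, 1]. The SAM-style
  fudge factor `s0` is exposed and defaults to 0. FDR is estimated separately
  per metric and per contrast; nothing is pooled across metrics.

* **Effect sizes on the raw scale.** The ratio of untransformed group means
  (zeros included) is the field's reporting unit; a protein never seen in the
  control gets ratio ∞ (it passes any finite cutoff), a protein absent from
  both groups gets an undefined ratio (it fails). The bounded **enrichment
  percentage** 100·bait/(bait + control) expresses the same quantity on a
  0–100 scale and keeps control-absent proteins plottable without
  pseudocounts; the two are linked by pct = 100·r/(1 + r), an identity the
  test suite checks at 1e-9.

## The hit definition

`call_hits()` applies, by default: PA ratio ≥ 1.5, PA FDR ≤ 0.05, PSM ratio ≥
1.5, PSM FDR ≤ 0.05, and at least 1 average bait PSM per injection. The 1.5
cutoff is the TurboID/BioID field-standard enrichment floor and is also what
the retrospective calibration (below) tends to suggest on well-behaved data;
the minimum-PSM rule removes proteins quantified on so little spectral
evidence that their PA p-values are unreliable.

A design choice worth spelling out: the **wildtype contrast is not part of
the default hit definition** (`require_wt_contrast = FALSE`). When wildtype
labeling is negligible — which is precisely what a successful experiment
shows — most proteins have too few nonzero wildtype measurements for any
t-test, and a rule that untestable contrasts fail would reject proteins for
having *maximal* evidence of enrichment. The wildtype arm instead serves as a
qualitative negligibility check (its median intensity relative to the control
is asserted in the tests), and the switch remains available for designs with
substantial wildtype signal.

`filter_funnel()` reports survivors after each criterion in order; since the
definition is a conjunction, the end count is order-invariant (tested), and
raising any threshold can only shrink the hit set (property-tested).

## Retrospective threshold calibration

Thresholds in PDL studies are justified after the fact by how many
database-curated partners of the bait they retain. `known_recovery_curve()`
counts known interactors at ratio ≥ c over a cutoff grid (default: 21
geometric points from 1 to 4, spanning the range where such cutoffs are
debated), fits count ~ log2(c) by least squares — log2 to match the log-ratio
axis convention and the package's transform default — and suggests the grid
point with the smallest absolute residual, ties toward the smaller cutoff.
Counting is over all proteins, not only FDR-passing ones; both readings are
possible and the stricter one can be had by subsetting the results first.

Two companion diagnostics stratify distributions rather than count:
`fdr_density_by_annotation()` (FDR by known-interactor status — known
partners should pile up at low FDR) and `pvalue_distribution_by_psm()`
(PA p-values under minimum-average-PSM rules ≥0, >0, ≥1 — restricting to
better-sampled proteins should raise the fraction at p ≤ 0.05).

## Network stratification

`degree_stratify()` assigns each hit its breadth-first shortest-path depth
from a focal protein over interaction edges with confidence score ≥ 0.4 (the
conventional medium-confidence floor); depth 1/2/3 = primary / secondary /
tertiary interactor, deeper or disconnected = unreached. Curated edges
without scores always survive the filter, because curated-database exports
typically carry no score. Symbols are matched case-insensitively with an
optional alias map, since murine and human symbol conventions are routinely
mixed in such lists. Intermediate nodes on a path need not themselves be
hits; a stricter hits-only neighborhood can be had by subsetting the edge
list. `filter_de_table()` provides the generic fold-change/adjusted-p
significance filter used for orthogonal whole-proteome comparisons,
defaulting to non-strict inequalities (≥ 2-fold, adjusted p ≤ 0.05) with a
strict switch.

## What the generator simulates — and what it does not

`simulate_pdl_experiment()` draws, on the log2 PA scale, a per-protein
baseline ~ N(`background_mu` = 20, `background_sigma` = 3) (log-normal
intensities spanning ≈ 3–4 orders of magnitude), a shared
(protein × experiment) batch effect (sd 0.5) so that runs cluster by
experiment in PCA, and injection noise (sd 0.3). True interactors
(10% of proteins by default) add a bait-only enrichment
~ N(`log2_effect_mean` = 2, sd 0.5). Wildtype intensities are divided by 50
(negligible labeling). Control values of true interactors are zeroed with
probability 0.15 per run: the ligase-only control labels promiscuously, so
most genuine interactors still show background-level control signal, and
run-level structural zeros are the exception rather than the rule. PSM counts
are Poisson with mean proportional to the *linear* peak area (6 expected
counts at the reference intensity 2^20): spectral sampling scales roughly
linearly with abundance over the detection range, which both couples the two
metrics and leaves a realistic stratum of proteins below 1 PSM per injection.
A rate proportional to log-intensity was considered and rejected: it
compresses a 4-fold enrichment into a ~1.3-fold PSM change, making the
package's own PSM ratio criterion unsatisfiable on data it is meant to
emulate.

Two deliberate idealizations:

* **True interactors are drawn from the detectable part of the abundance
  distribution** (baseline truncated at `background_mu − 0.5·background_sigma`;
  `interactor_min_z` disables this). A protein the instrument cannot sample at
  a few spectra per run can be neither established nor curated as an
  interactor, so spiking interactors into the undetectable tail would score
  the pipeline against targets no method could recover.
* Effects are protein-level constants; there is no peptide-level structure,
  retention-time drift, ionization competition, or shared-peptide ambiguity.

Consequently, passing tests on simulated data show that the statistics,
filters and bookkeeping do what they claim under the stated generative model
— not that any particular real experiment will reach the same recovery.

`simulate_annotation()` (coverage / contamination of the true set),
`simulate_edge_list()` (scored edges wiring true interactors at depths 1–3
around the focal protein plus random background) and `simulate_de_table()`
complete the inputs needed to exercise annotation and calibration.

## Numerical conventions and degenerate inputs

* Blank cells in quant files become 0 (non-detection) with a reported count;
  non-numeric cells are errors, never silent NA.
* Zeros enter untransformed means (ratio, enrichment %) but never the t-test.
* PCA imputes missing log values to the observed minimum and drops
  zero-variance proteins; fewer than two informative proteins flags the
  result degenerate instead of erroring.
* Calibration with an empty known set returns a zero curve with a degenerate
  (NA) regression; ties in the suggested-cutoff rule resolve to the smaller
  cutoff.
* Depth stratification ignores duplicate edges and row order; self-loops are
  dropped on input.
* All stochastic steps (simulation, random permutations, annotation
  sampling) are seeded; exhaustive permutation mode is seed-independent by
  construction, and `run_pipeline()` derives all stage seeds from one master
  seed so a rerun is byte-identical.

## Problem sizes

The test suite exercises exact oracles on 3-vs-3 toys (20 label splits,
enumerated both by the package and by an independent brute-force oracle) and
statistical properties on simulations of 150–2000 proteins at the 27-run
design with 250 random permutations — sizes chosen so the full suite runs in
well under a minute while leaving the binomial error bands meaningful. The
acceptance script uses 2000 proteins throughout.

## Known limitations

* The permutation null is computed from the same matrix that carries the
  spiked effects; with many strong effects the null tail is inflated and the
  FDR becomes conservative — visible in the tests as empirical FDP well
  below nominal.
* The t-test excludes zeros, so a protein absent from the control in most
  runs is tested on few values; its evidence is carried by the ratio and
  enrichment percentage instead. This is inherent to the
  zeros-as-missing convention, which we prefer to imputation.
* Symbol-based matching is only as good as the alias map supplied;
  accession-level matching is supported wherever both tables carry
  accessions.
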