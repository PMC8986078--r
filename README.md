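# isletmorph

Quantitative analysis of pancreatic-islet cytoarchitecture and of the
cell-behaviour assays used to explain its disruption by Notch/Ephrin
signaling — packaged for R, with a synthetic-data layer so that every
stage runs and is testable without microscopes or tissue.

Mouse islets are organized as a beta-cell **core** wrapped by an
alpha/delta-cell **mantle**. Notch gain-of-function in beta cells
disrupts this architecture (more glucagon-positive alpha cells inside
the core), impairs pseudoislet re-aggregation of dispersed islet cells,
and is linked to ephrin-A5-mediated contact repulsion, with matching
signatures (higher RBPJ activity, enriched EPH-Ephrin components) in
metabolically inflexible human beta cells. isletmorph implements the
measurements behind each of those claims:

- **Architecture** — partition an islet's cells into core and mantle
  (mantle = centroid within `mantle_depth` of the islet boundary,
  default 1.5 × median cell diameter) and report per-type core
  percentages and the Gcg+/Ins+ cell ratio.
- **Dispersion degree** — for a field of aggregating cells, all
  pairwise distances normalized by `d_max`, the empirical CDF
  F(t) = P(d/d_max ≤ t), and the statistic `1 − ∫₀¹ F(t) dt` (exact
  step-function integral): 0 for a perfect aggregate, → 1 for scattered
  cells.
- **Coated-surface avoidance** — enrichment = (fraction of beta cells
  on coated pixels) / (coated areal fraction), plus a one-sided
  permutation test against complete spatial randomness.
- **Segmentation** — threshold + distance-transform watershed
  instance segmentation of multi-channel images into per-cell records
  with marker-rule typing (via EBImage).
- **Pathway scoring** — per-cell gene-set activity means, preranked
  gene-set enrichment (weighted running-sum ES, gene-set permutation
  null, sign-matched NES), and regulator–component Pearson correlation.
- **Simulators** — a differential-adhesion Metropolis cell-sorting
  model with a tunable beta-cell contact-repulsion perturbation, a
  Neyman–Scott pseudoislet generator, blob-field coating assays, and
  group-structured activity/expression matrices; all seeded and
  deterministic.

## Worked example

Simulate a control islet at the shipped study conditions, measure its
architecture, and compare control and Notch-active cohorts:

```r
library(isletmorph)

ctl_cfg  <- read_sorting_config(system.file("extdata", "control.yaml", package = "isletmorph"))
nicd_cfg <- read_sorting_config(system.file("extdata", "nicd.yaml",  package = "isletmorph"))

ctl_cfg$seed <- 1
ctl <- simulate_islet(ctl_cfg)
ctl
#> <islet_pattern> 100 cells, polygon boundary, 1 um/px
#>   cell_type     n
#> 1 alpha        20
#> 2 beta         70
#> 3 delta        10

measure_architecture(ctl, boundary = "reconstruct")
#>   n_alpha core_pct_alpha core_pct_beta ratio_gcg_ins mantle_depth
#> 1      20             15          68.6         0.286         10.5
```

15 % of this control islet's alpha cells sit in the core versus 69 % of
its beta cells — the sorted mantle-core phenotype. Over cohorts of 12
islets per condition:

```r
core_a <- function(cfg, n, base) sapply(seq_len(n), function(k) {
  cfg$seed <- base + k
  measure_architecture(simulate_islet(cfg), boundary = "reconstruct")$core_pct_alpha
})
ctl_v  <- core_a(ctl_cfg, 12, 100)
nicd_v <- core_a(nicd_cfg, 12, 200)
compare_groups(ctl_v, nicd_v)
#>       t    df         p mean_a sem_a mean_b sem_b method
#> 1 -5.49    22 0.0000163     25  3.48   51.7  3.39 student
mean(nicd_v) / mean(ctl_v)
#> [1] 2.07
```

The perturbed cohort has roughly twice the control core alpha-cell
percentage even at this small demo size (the fixtures are calibrated to
a ground-truth ratio of 2.5, which the 50-islet-per-arm acceptance run
recovers). The other assays follow the same pattern — simulate, then
measure:

```r
f_tight <- simulate_pseudoislet_field(200, 1, cluster_sd = 10,  field_size = 512, seed = 3)
f_loose <- simulate_pseudoislet_field(200, 1, cluster_sd = 120, field_size = 512, seed = 3)
dispersion_degree(f_tight$points, d_max = sqrt(2) * 512)$dispersion_degree  # 0.0264
dispersion_degree(f_loose$points, d_max = sqrt(2) * 512)$dispersion_degree  # 0.2215

assay <- simulate_coating_assay(0.4, occupancy_ratio = 0.3, n_cells = 400, seed = 4)
avoidance_permutation_test(assay, n_perm = 999, seed = 5)
#> <avoidance_result> beta cells (n = 400): f_on = 0.175, f_area = 0.400, enrichment = 0.437
#>   CSR permutation (999 perms, avoidance): z = -9.35, p = 0.001
```

Result objects have `tidy()`, `glance()` and `autoplot()` methods, and
`run_pipeline()` chains simulate → architecture → report over cohort
configs with a reproducibility manifest. A thin command-line wrapper
lives at `inst/scripts/isletmorph-cli.R`. The methods vignette
(`vignettes/islet-architecture-methods.Rmd`) documents the models,
defaults and design decisions.

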