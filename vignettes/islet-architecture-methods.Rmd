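---
title: "Models and methods behind isletmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind isletmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletmorph)
```

isletmorph quantifies pancreatic-islet cytoarchitecture and the
downstream signatures of Notch/Ephrin-driven disruption: core/mantle
composition of alpha, beta and delta cells, the "dispersion degree" of
pseudoislet re-aggregation assays, beta-cell avoidance of ligand-coated
surfaces, and gene-set activity/enrichment scoring of single-cell
regulator-activity matrices. Because the biological material (pancreas
sections, pseudoislet cultures, coated-slide assays, single-cell
profiles) is not shippable, every analysis is paired with a synthetic
generator that emulates the relevant data-generating process with known
ground truth. This vignette records the models, the parameters that
matter, and the design decisions taken where the underlying publications
of this field typically leave the computation under-specified.

## The cell-sorting simulator

Murine islets show mantle-core organization: a beta-cell core wrapped by
an alpha/delta mantle. The simulator reproduces this with the minimal
physics that can express it — the differential adhesion hypothesis on
hard disks. `n_alpha + n_beta + n_delta` cells of radius `cell_radius`
(default 3.5 µm) live in a circular domain (default radius 57 µm,
about a 100-cell mouse islet cross-section at moderate packing). Pairs
closer than 2.5 cell radii are "in contact" and contribute a type-pair
energy from a symmetric 3×3 table; lower is more adhesive. The default
table is

```{r}
default_adhesion()
```

beta–beta contacts are strongly favourable, beta–nonbeta weakly
favourable, and nonbeta pairs weaker still. Dynamics are Metropolis
Monte Carlo: each sweep attempts one Gaussian displacement per cell
(sd = `cell_radius / 2`), rejecting moves that overlap another cell or
leave the domain and accepting uphill moves with probability
`exp(-dE / temperature)`. This is the simplest ergodic move set for an
off-lattice adhesion model; no swap or cluster moves are used. At the
default `temperature = 0.8` a beta–beta bond (−2) breaks rarely but not
never, which keeps the system liquid enough to sort; 15 000 sweeps
anneal a 100-cell islet in about a second and leave the
core-composition metrics stationary to within replicate noise.

The Notch/Ephrin perturbation is modelled cell-autonomously: a fraction
`frac_perturbed_beta` of beta cells is flagged at initialization and
every contact involving a flagged cell pays an extra nonnegative energy
`repulsion_beta`. Flags never change, mirroring a cell-intrinsic
genetic perturbation. Rising `repulsion_beta` progressively dissolves
the beta core and lets alpha/delta cells invade it, which is exactly the
phenotype the architecture module measures.

The shipped conditions `inst/extdata/control.yaml` and
`inst/extdata/nicd.yaml` differ only in the perturbation
(`repulsion_beta` 0 vs 2, `frac_perturbed_beta` 0 vs 1). No
quantitative effect size for ephrin-driven repulsion is available from
experiments, so the perturbed fixture is calibrated: `repulsion_beta`
was scanned and frozen at the value where the ground-truth ratio of
perturbed to control core alpha-cell percentage is 2.5, the effect size
reported for Notch-active mouse islets. The calibration is a modelling
choice, recorded in the fixture files, and everything downstream treats
it as fixed.

Energy per sweep is recorded in the pattern's metadata; at near-zero
temperature the time-averaged trace is nonincreasing, which the test
suite uses as a dynamics sanity check. All randomness in a call flows
from one seeded generator, so identical config + seed is bit-identical.

What the simulator deliberately is not: a vertex or Cellular Potts
model, a 3D model, or a model of vasculature, innervation or
macrophages. Cells are equal-sized disks; adhesion is pairwise and
isotropic. Conclusions from passing tests are therefore about the
measurement pipeline's behaviour on sorted/unsorted point patterns, not
about islet biophysics.

## Rendering and segmentation

`render_islet()` draws each cell as a filled disk of constant amplitude
into the channels of its type (`ins`, `gcg`, `sst`, plus a pan-cell
`nuc` channel), with optional additive Gaussian noise, and returns the
true instance labels. `segment_cells()` then mirrors a standard Fiji
workflow: Gaussian smoothing (`smoothing_sigma`, default 1 px), Otsu or
fixed thresholding, watershed on the distance transform of the binary
mask, removal of objects below `min_cell_area`, per-cell channel means,
and marker-rule typing (highest passing channel wins; cells passing no
rule are `other`). The published workflows this emulates never state
their thresholds or minimum object sizes; Otsu was chosen as the
standard parameter-free default, and the watershed seed scale is tied to
`min_cell_area` (neighbourhood radius ≈ the expected cell radius).
Coordinates are 0-based pixel indices, pixel-center convention, x
rightward and y downward; micrometre conversions use `pixel_size`.
Per-cell intensity is a plain mean over labelled pixels with an optional
constant-offset background subtraction (off by default).

On noiseless renders of non-touching disks the suite requires ≥ 95 % of
ground-truth cells recovered with sub-pixel centroid error; densely
packed sorted islets will always merge some touching same-channel disks,
which is why cohort architecture below is measured on cell tables
directly rather than through a render/segment round trip.

## Core/mantle architecture

No published definition of the islet "core" exists in this literature;
the package operationalizes the mantle as the outermost cell shell: a
cell is mantle iff its centroid lies within `mantle_depth` of the islet
boundary, with `mantle_depth` defaulting to 1.5 × the median equivalent
cell diameter (≈ one cell layer, 10.5 µm at the default geometry). The
partition is purely geometric — permuting type labels cannot change
zones — and is exact for polygon boundaries, distance-transform-based
for mask boundaries. When only cells are available the boundary is
reconstructed as the hole-filled morphological closing of the union of
cell disks (closing radius two cell radii). Cohort measurements on
simulated islets use this reconstruction rather than the generating
domain, so the pipeline is never handed information a microscopist would
not have. Composition metrics count cells (not marker area), matching
the cell-counting wording of the assays they emulate; types with zero
cells report a missing core percentage rather than zero, and the
glucagon-to-insulin ratio is the alpha/beta count ratio.

## Dispersion degree

For a field of segmented cells the statistic is: all pairwise Euclidean
distances, normalized by `d_max` (image diagonal by default; distances
beyond `d_max` clip to 1), the right-continuous empirical CDF of the
normalized distances, and its exact integral over [0, 1]. For a step
CDF the integral is `1 - mean(t)`, so the dispersion degree `1 - auc`
equals the mean normalized distance — computed exactly, with no
binning. Direction: tight aggregates → CDF rises early → AUC near 1 →
dispersion near 0; impaired aggregation raises the statistic. Whether
the original normalization used the image diagonal or the per-image
maximum distance is not recoverable from the published description;
the image diagonal is the default because it keeps fields of equal size
comparable, and `d_max` is always reported in the result.

The pseudoislet generator is a Neyman–Scott cluster process (uniform
cluster centres, isotropic Gaussian offspring, out-of-field offspring
redrawn), rendered as filled disks. Its `cluster_sd` dial maps
monotonically onto the dispersion degree, which the acceptance suite
checks as a rank correlation across a five-level grid.

## Coated-surface avoidance

Two algorithms are reported side by side. Algorithm 1 is the
occupancy-enrichment ratio: the fraction of selected-type cells whose
centroid lies on coated pixels, divided by the coated areal fraction
(1 = no preference, < 1 = avoidance). Membership is by centroid pixel —
`(x, y)` belongs to pixel `(floor(x), floor(y))` — matching
cell-counting colocalization language; an area-overlap variant (mean
coated fraction of each cell's disk) is available. Algorithm 2 is a
permutation test against complete spatial randomness: cell positions
are resampled uniformly over the field, the observed on-coated fraction
is ranked in the null sample with the add-one correction, one-sided
lower-tail by default because the scientific hypothesis is avoidance.
The synthetic assay thresholds a Gaussian-smoothed noise field at the
quantile matching the requested coated fraction and places cells by
rejection sampling at the requested coated/uncoated odds. The test's
type-I error at the 5 % level is required to sit in [0.02, 0.08] over
500 null simulations; the add-one correction makes it slightly
conservative, which is the standard trade-off.

## Pathway scoring

The single-cell analyses are emulated at the level of their statistical
structure: the generator draws regulator activity N(0, 1) for healthy
(H) cells and N(delta, 1) for metabolically inflexible (MI) cells, and
each component feature as `rho * regulator + sqrt(1 - rho^2) * noise`,
so the within-group correlation with the regulator is `rho` and a
regulator shift of `delta` propagates to component means as
`rho * delta`. (With `delta != 0` the pooled-population correlation
slightly exceeds `rho`; the generator documents rather than corrects
this, since the pooled scatter is exactly what the corresponding
figures display.) Gene-set activity is the plain mean over member
features, with absent members dropped and reported.

Preranked enrichment implements the weighted Kolmogorov–Smirnov-style
running sum: hits add `|score|^weight` normalized over hits, misses
subtract `1/(N - N_hits)`, and the enrichment score is the signed
maximum deviation. `weight = 1` with 1000 gene-set permutations is the
conventional default; `weight = 0` is retained because it admits exact
small-case oracles and is invariant to monotone rescaling of the
ranking. The null is gene-set resampling (the only permutation scheme
preranked input admits); NES divides the ES by the mean |null ES| of
matching sign, and the p-value is the one-sided matching-sign frequency
with the add-one correction. An independent brute-force walk of the
ranking, and an external implementation, serve as oracles in the tests.
Regulator-component association is the standard Pearson correlation
with its t-distribution p-value; constant inputs are a reported error
rather than a silent `NaN`.

## Pipeline and statistics

`run_pipeline()` chains simulate → architecture → report over named
cohorts with per-islet seeds derived deterministically from the global
seed, writes per-cohort cell tables, per-islet metrics, mean ± SEM
summaries and (for two cohorts) per-metric two-sided t tests, and emits
a manifest (config hash, seed, package version, file list) that is
checked for completeness against the output directory. The two-group
comparison defaults to the classical pooled-variance Student t test,
with Welch as an option; zero within-group variance in both groups is a
reported degenerate-variance error. One-way ANOVA with Dunnett-style
contrasts is out of scope: no pipeline stage compares more than two
groups against a control.

## Problem sizes and numerical choices

The test and acceptance workloads use 100-cell islets (50 per cohort
arm, 20 per dose level over five repulsion levels), 500 null
simulations for permutation calibration, 1000 simulations for null
p-value uniformity at 199 permutations, and 2000-cell CSR assays —
sizes at which every Monte Carlo band in the suite is comfortably wider
than its standard error. Ties in the watershed are resolved by the
deterministic scan order of the underlying image library; dispersion
and enrichment integrals are exact rather than binned; all stochastic
stages take explicit seeds and restore the caller's RNG state.

## Known limitations

- The sorting model is 2D, single-islet, equal-radius and adhesion-only;
  it cannot express delamination, proliferation or death.
- Segmentation is classical thresholding + watershed; heavily
  overlapping or low-contrast cells will merge, and no learned model is
  provided.
- The dispersion statistic summarizes one distance distribution; it is
  not a substitute for Ripley-type second-order analysis.
- The activity-matrix generator reproduces first- and second-moment
  structure only; real single-cell matrices have heavier tails,
  dropout and correlated noise that it does not emulate. Passing tests
  demonstrate correctness of the measurement code under the stated
  models, not fidelity of those models to any particular dataset.
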