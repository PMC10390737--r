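# slicequant

Quantitative image and expression analysis of focal injury in organotypic
brain-slice cultures.

A controlled cortical impact on a cultured cortical slice leaves a focal
contusion: dead cells (propidium-iodide signal) concentrate at the impact
site and fade radially; the MAP-2 dendritic network thins toward the core;
microglia near the core round up from ramified to amoeboid shapes; injury
genes and biomarkers shift. `slicequant` implements the measurement chain
used to quantify all of this from single-channel fluorescence stacks and
qPCR Ct tables, and pairs it with a synthetic slice-image generator so that
every stage can be validated against known ground truth. It is written for
researchers analysing slice-injury experiments and for anyone who wants a
tested, scriptable re-implementation of this common ImageJ workflow.

## What it computes

* **Radial cell-death profiling** — integrated density (sum of intensities)
  normalized by area, per concentric 0.5 mm ring centred on the lesion
  (half-open rings, pixel-centre distances), summarized as the trapezoidal
  AUC of normalized density against ring midpoint distance (intensity·mm).
* **Neurite morphometry** — per ROI: background floor (`max(I − 1200, 0)`),
  disk median filter (radius 5 px), Li minimum cross-entropy threshold on
  the pooled z-stack, extended-focus OR-projection, topology-preserving
  thinning, and skeleton-graph metrics: branch count (junctions merged when
  8-adjacent, no endpoint pruning), longest branch (μm; axial steps count
  `pixel_size`, diagonal `√2·pixel_size`), and network density (skeleton
  length per ROI area).
* **Glial morphometry** — percent stained area over focal planes, and
  single-cell shape descriptors behind the inclusive 40–500 μm² gate:
  area, corrected boundary-step perimeter, convex-hull Feret diameter, and
  circularity `4πA/P²` (clamped at 1).
* **ΔΔCt expression** — `log2FC = −(ΔCt − mean ΔCt of controls)` against a
  reference gene (RPL27 by default), plus Shapiro–Wilk-gated group
  statistics: t / Mann–Whitney, one-way ANOVA + Tukey, two-way ANOVA
  (type-II) + Sidak.
* **Synthetic slices** — radially decaying cell-death signal, random-walk
  filament networks with per-region density factors, non-overlapping
  ramified/amoeboid cell populations, and planted Ct tables; Poisson +
  Gaussian noise; every generator is a pure function of (spec, seed) and
  returns per-object ground truth.

## Worked example

Skeleton metrics of a hand-built plus-shaped skeleton (two perpendicular
41-pixel lines crossing at their centres, 0.21 μm pixels):

```r
library(slicequant)
sk <- matrix(FALSE, 45, 45)
sk[23, 3:43] <- TRUE
sk[3:43, 23] <- TRUE
analyze_skeleton(sk, pixel_size = 0.21)
#>   n_branches longest_branch_um total_length_um network_density
#> 1          4               4.2            16.8       0.1881246
```

Four branches — one per arm — each measured from the cross centre to its
endpoint: 20 steps × 0.21 μm = 4.2 μm.

A synthetic injured slice, profiled radially (400 × 400 px at 10 μm/px,
Gaussian lesion of amplitude 1000, σ = 500 μm over baseline 100):

```r
spec <- slice_spec(seed = 7)
sim  <- simulate_pi_channel(spec)
geom <- lesion_geometry(spec$lesion_center, spec$pixel_size, n_rings = 4)
prof <- radial_profile(sim$image[, , 1], geom)
round(prof$normalized_density, 1)
#> [1] 886.7 414.4 149.5 103.2
round(profile_auc(prof), 1)
#> [1] 529.4
```

The measured ring means track the planted profile (the analytic ring
averages are 886.9, 414.1, 149.7, 103.1) and the AUC condenses the injury
burden into one number; an uninjured slice with amplitude 80 yields an AUC
near 180.

An end-to-end simulated study (CTRL, TBI, TBI+MSC-sec) is run by
`run_study(run_config(...))`; see `analysis/01_simulate.R` through
`analysis/06_study.R` for the scripted workflow that writes TIFFs,
per-stage CSVs and a condition-level summary under `results/`.

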