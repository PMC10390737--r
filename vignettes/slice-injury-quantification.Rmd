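---
title: "Quantifying focal injury in organotypic slice cultures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying focal injury in organotypic slice cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicequant)
```

## The measurement problem

A controlled cortical impact on a cultured brain slice produces a focal
contusion: dead cells accumulate around the impact site, dendritic networks
thin out toward the core, astrocytes and microglia react, and microglia in
particular shift from a ramified (resting) to an amoeboid (activated)
morphology. `slicequant` implements the image- and expression-analysis
procedures used to quantify these phenotypes from fluorescence microscopy
(one stain per channel: a cell-death dye such as propidium iodide, MAP-2 for
dendrites, GFAP for astrocytes, Iba-1 for microglia) and from qPCR Ct
tables, together with a synthetic slice-image generator that provides ground
truth for every stage.

All spatial conventions are shared across modules: coordinates are 0-based
`(row, col)` pixel positions; distances are Euclidean between pixel centres,
in micrometres; intervals are half-open. The concentric geometry uses 0.5 mm
rings: the *lesion* area is `[0, 500)` um from the lesion centre,
*perilesion* `[500, 1000)` um, *periphery* beyond 1 mm; a distance of
exactly 500 um is perilesion.

## Radial cell-death profiling

The cell-death channel is summarized as *integrated density* (the sum of
pixel intensities over a region) normalized by region area. "Area" here is
the mask's pixel count, so the normalized form is a mean intensity;
physical-area normalization differs only by the constant `pixel_size^2` and
is available via an option. The radial profile evaluates this per concentric
ring; rings clipped by the image border carry an in-image coverage fraction
and rings below 50% coverage are flagged for exclusion (the threshold is an
argument). Empty rings are reported as missing, never as zero. The profile
is summarized by the trapezoidal area under normalized density against ring
midpoint distance in millimetres; whether to integrate against physical
distance or ring index is not uniquely determined by common practice, so
physical distance is the default and index mode is a flag.

The whole-slice measurement needs a slice outline; when none is supplied it
is derived by Otsu thresholding a Gaussian-smoothed copy of the image, a
deliberately simple stand-in for a hand-drawn outline.

## Neurite morphometry

The segmentation pipeline runs per ROI in this order: (1) background floor —
`max(I - 1200, 0)` per pixel, reading "imposing a minimum gray value of
1,200" as the usual ImageJ floor-subtraction idiom (a pure clip-to-floor
variant is behind a flag); (2) median filter over a disk of radius 5 px with
replicated borders; (3) Li minimum cross-entropy threshold computed once on
the pooled z-stack histogram (per-slice mode available), iterating
`t <- (mb - mf) / (log mb - log mf)` from the image mean until successive
thresholds differ by under 0.5 gray values, with foreground strictly above
the threshold; (4) extended focus, the logical OR projection over z;
(5) Guo–Hall two-subiteration thinning to an 8-connected one-pixel skeleton
(idempotent at convergence); (6) skeleton-graph analysis.

The skeleton graph classifies pixels by their 8-neighbour count: junctions
(>= 3), endpoints (<= 1), slabs (2). Adjacent junction pixels merge into a
single node — without this, every thick crossing spawns spurious one-pixel
branches. Branches are pixel paths between nodes; nothing terminating at an
endpoint is pruned; an isolated closed loop counts as one branch. Lengths
sum per-step distances (`pixel_size` axial, `sqrt(2) * pixel_size`
diagonal); a branch ending at a multi-pixel junction is anchored at the
junction's pixel centroid, the convention of standard skeleton analyzers,
so each arm of a symmetric cross measures from the cross centre. *Network
density* has no universally agreed formula; it is implemented as total
skeleton path length per ROI area (um/um^2), with the skeleton-pixel
fraction available as an alternative.

ROIs default to 4 per concentric area, placed at the cardinal directions on
each annulus mid-radius; explicit ROI tables override this, since real
acquisitions are operator-placed. Area summaries average the 4 ROIs; for
uninjured slices, where the areas do not differ, the pooled mean of all 12
ROIs is the conventional summary and is also returned.

## Glial morphometry

Percent stained area binarizes each of the first five focal planes with an
automatic threshold and reports foreground percentage per plane and its
mean. Otsu is the default (the binarization method for these channels is
not standardized; Li is the configurable alternative for consistency with
the neurite channel); a constant plane is reported missing with a warning,
except the all-zero case, which is 0% by an explicit rule.

Single-cell analysis labels 8-connected components, applies the inclusive
40–500 um^2 size gate (`area = pixels x pixel_size^2`) selecting single
microglia, and measures per cell: area; perimeter by the Vossepoel–Smeulders
corrected boundary-step estimator
(`0.980 N_axial + 1.406 N_diagonal - 0.091 N_corner` on the Moore-traced
outer boundary), which removes most digitization bias of raw step counting;
Feret diameter as the maximum pairwise distance between convex-hull vertices
of boundary pixel centres (pixel-centre convention: a 1 x n line has Feret
`(n-1) * pixel_size`; boundary-corner conventions differ by at most one
pixel); and circularity `4 pi A / P^2`, clamped at 1 because coarse
digitizations can overshoot. A single-pixel component takes defined
degenerate values (area one pixel, Feret 0, circularity 1). Per-image
summaries are arithmetic means over retained cells; zero retained cells
yield a missing record, not zeros.

One estimator limitation is worth stating plainly: chain-code perimeter
estimators are calibrated for boundaries sampled near their resolution
limit. Resampling the same blocky region on a finer grid (e.g. nearest-
neighbour upscaling with halved pixel size) turns diagonal boundary runs
into fine staircases that any weighted-step estimator over-measures — a 45°
edge is overestimated by ~26% in the staircase representation. Area and
Feret are stable to a few percent under such rescaling; the perimeter (and
hence circularity) is reproducible only to roughly 10–15%, and the test
suite asserts exactly that. Comparisons should therefore use a fixed
acquisition scale, which is how the shape gate and descriptors are used
here.

## Expression analysis and group statistics

Relative expression uses the delta-delta-Ct scheme with RPL27 as the
reference gene: `dCt = Ct(gene) - Ct(ref)` per sample, baselined against
the *mean* control-group dCt per gene (mean-baselining is the common choice
where no sample pairing exists; a geometric-mean option is off by default),
and reported as `log2FC = -ddCt`, making the control mean 0 by
construction. Adding any constant to all of a sample's Ct values, reference
included, cancels exactly.

Group comparisons follow a normality gate: Shapiro–Wilk per group at alpha
= 0.05, all groups must pass, otherwise the rank branch (Mann–Whitney,
Kruskal–Wallis) is used; groups of identical values fail the gate by
definition. The parametric branch uses Welch/pooled t-tests, one-way ANOVA
with Tukey HSD, or two-way ANOVA (e.g. region x treatment) with Sidak-
adjusted pairwise comparisons within the conditioning factor; unbalanced
two-way designs use type-II sums of squares. Post-hoc tables always carry
both unadjusted and adjusted p-values, and adjusted values can never
undercut unadjusted ones. No correction is applied across genes or
analytes beyond the named post-hoc procedures.

## The synthetic slice generator

The generator emulates the three injury phenotypes with known ground truth.

* **Cell-death channel** — noiseless signal
  `baseline + amplitude * exp(-r^2 / (2 sigma^2))`, sigma 500 um by
  default, so the signal peaks at the lesion core and decays smoothly into
  the rings.
* **Neurite channel** — filaments seeded by a Poisson process at
  `filament_rate * d(region)` per 100 x 100 um tile (`d` in [0,1] per
  concentric area, sharing the analyzer's geometry), grown as biased random
  walks (1 px steps, direction jitter up to 0.4 rad, branching probability
  0.04 per step with the branch inheriting the remaining step budget),
  rendered 3 px wide on one random z-slice. Default filament lengths are
  15–25 steps (60–100 um at the simulated 4 um/px), keeping each filament
  small relative to the 0.5 mm ring geometry the way dendritic segments
  are in real slices; longer filaments would straddle region boundaries
  and blur planted regional contrasts for purely geometric reasons. Ground
  truth records one row per filament (seed, region, realized steps, path
  length).
* **Cell channel** — non-overlapping cells by rejection sampling with a
  bounded attempt budget; P(amoeboid) interpolates linearly from the core
  fraction at r = 0 to the periphery fraction at the farthest corner.
  Amoeboid cells are filled ellipses (designed area drawn from 80–300
  um^2); ramified cells are a ~3 um soma with 3–6 one-pixel processes of
  8–18 um. Designed areas are analytic for ellipses and rendered pixel
  counts for ramified cells.
* **Noise** — Poisson shot noise at `noise_gain` photons per intensity unit
  plus Gaussian read noise, the photon-limited confocal model; background
  900 and foreground 4000 on the 16-bit scale were chosen so that the 1,200
  background floor and Li thresholding exercise realistically. Every
  generator is a pure function of (spec, seed) and leaves the session RNG
  untouched.
* **Ct tables** — `Ct = baseCt - log2FC * treated + N(0, sd)` with the
  reference gene independent of group; a second treated arm supports
  three-group designs.

What the generator does *not* emulate: optics (no point-spread function),
3D structure beyond random z-assignment, vasculature, infiltrating cells,
staining variability, or uneven illumination. Passing recovery tests on
synthetic data therefore validates the measurement chain — geometry,
thresholding, topology, statistics — not robustness to the full messiness
of real acquisitions.

## Problem sizes and scaled-down geometry

Real acquisitions in this setting are ~0.21 um/px (neurites) and 0.31 um/px
(glia), which over a multi-millimetre slice would mean >10^8 pixels per
channel. The simulated studies keep the physical geometry (0.5 mm rings,
the 40–500 um^2 gate, the 1,200 floor) but use coarser sampling chosen once
as the package's study design: the cell-death field is 400 x 400 px at 10
um/px, the neurite field 800 x 800 px at 4 um/px (sized so periphery ROIs
keep >= 230 um margin from the field edge — the seeding process is
truncated at the border, and ROIs near it would be systematically
depressed), and the cell field 1100 x 1100 px at 1 um/px with the lesion
centre at (250, 250) so the field reaches beyond 1 mm. Because synthetic
filaments are rendered 3 px wide, simulation studies run the median filter
at radius 2 — proportionate to the rendered width in the same way radius 5
is proportionate to a ~1 um / 5 px dendrite at acquisition resolution; the
radius-5 default remains on the function surface. Simulated studies use 2–3
slices per condition and Monte-Carlo loops use 200–1,000 replicates, sizes
at which every planted effect in the design is comfortably detectable.

## Numerical and degenerate-input choices

Li thresholding requires positive values for its logarithms; stacks
containing values below 1 are shifted up by `1 - min` for the iteration and
the threshold is shifted back. The cross-entropy criterion is flat across
empty intensity gaps, so on well-separated histograms any threshold inside
the gap is equally optimal; tests therefore check criterion optimality, and
uniqueness only on overlapping mixtures. Constant stacks are a hard error
for thresholding, but a ROI that is constant *after* floor subtraction
(i.e. contains no signal above background) yields zero skeleton metrics —
the meaningful answer for a blank ROI. Division-by-zero paths (empty masks,
empty cell sets, fewer than two rings for an AUC) are explicit errors or
missing values, never silent zeros.

Determinism is treated as part of the contract: study runs derive per-slice
seeds from the base seed, outputs embed an MD5 hash of the YAML-serialized
configuration (excluding the output directory), rerunning a configuration
reproduces byte-identical CSVs, and the summary step refuses to combine
tables with different hashes.

## Known limitations

Beyond the perimeter rescaling bias and the generator's idealizations noted
above: ROI placement at cardinal directions is a convention, not a
validated reconstruction of operator choices; the Li threshold operates on
the full 16-bit histogram (tools that rescale to 8 bits first can differ
slightly); network density cannot be compared numerically to published
figure panels, which plot but do not print their values; and the skeleton
length recovered from rendered filaments saturates at high density when
filaments overlap and merge, which compresses—but, over the tested 0.1–1.0
density span, does not destroy—the linear relation between measured and
planted total length.
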