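---
title: "Quantifying cortical vascular networks: skeleton morphometry, local fractal complexity, and MR lesion segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical vascular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselfract)
```

## The problem

Fluorescent labeling of the endothelium ("vessel painting") renders the
entire cortical surface vasculature visible in a single wide-field image.
After a focal cortical impact, vessels are lost both at the impact site and,
more diffusely, across both hemispheres. This package quantifies that loss
along three complementary axes:

1. **Classical morphometry** — binarize the image, thin the vessels to a
   one-pixel skeleton, and count *junctions* (points where three or more
   branches meet), *total vessel length*, and *vessel density* (foreground
   area / region area).
2. **Fractal complexity** — map the *local connected fractal dimension*
   (LFD) at every vessel pixel and summarize its histogram by the peak
   location, the peak's relative frequency, skewness, and kurtosis.
3. **MR volumetry** — segment companion MR volumes by *hierarchical region
   splitting* (HRS) to estimate lesion volume, and process
   susceptibility-weighted acquisitions (SWI) with a negative-phase mask to
   detect hemorrhage.

Because no raw images are publicly deposited, the package ships a seeded
synthetic-data generator whose ground truth (segments, junctions, lengths,
phantom compartment masks) is exact, so that every stage of the pipeline is
testable end to end.

All rasters are R matrices indexed `[row, col]` with the origin at the top
left; volumes are arrays indexed `[row, col, slice]`. We use R's native
1-based indexing throughout.

## The synthetic vessel generator

`generate_vessel_network()` grows a branching network from trunks seeded on
the image border: each branch advances in steps of fixed length with a
jittered heading and splits into two daughters (at about ±45°) with a fixed
per-step probability. An integer occupancy grid assigns every drawn corridor
an id; a growing tip dies when its next step would enter a corridor other
than its own recent ones, which keeps segments from overlapping. Because
ablation and bookkeeping act on *segments* rather than pixels, the recorded
ground truth stays exact through every manipulation:

```{r generator, eval = FALSE}
cfg <- network_config(rng_seed = 1)      # 768 x 768 px at 20 um/px
net <- generate_vessel_network(cfg)
img <- rasterize_network(net, noise_sd = 0.02)
```

What the defaults emulate, and why:

* `pixel_size_um = 20`, 768×768 px — a ~15 mm wide axial cortical slab at
  wide-field resolution, large enough for 1/2/3 mm concentric rings around a
  lateral epicenter.
* `branch_probability = 0.85`, `step_length_px = 8`, 48 trunks — calibrated
  once so that the *unablated* network is dense enough for its LFD histogram
  to peak in the 1.3–1.6 range typical of healthy cortical plexus images.
  Sparser settings leave most vessels locally line-like (LFD ≈ 1).
* Widths 2–3 px and a clearance corridor wide enough that rasterized
  capsules of adjacent vessels never touch; junction recovery from the
  raster is then essentially exact (measured/truth ≈ 1.00 in our tests).
* `lesion_spec()` models the injury as segmentwise removal with probability
  `max(global, core × falloff(distance))`. The default `falloff = "flat"`
  removes `core = 0.9` of segments uniformly inside the lesion radius —
  matching the sharply delimited disruption zone an impactor tip produces —
  on top of a diffuse `global = 0.3` rarefication affecting both
  hemispheres. A linear taper is available (`falloff = "linear"`), but at
  the default 1.5 mm radius it dilutes the focal signature to below
  cohort-level sampling noise.

What the generator does **not** emulate: vessel caliber hierarchies
(Murray's law), anastomoses/loops, curvature statistics of real pial
vessels, uneven staining, and out-of-focus haze. Passing tests therefore
demonstrate that the *measurement pipeline* is correct and directionally
sensitive, not that the generator is a realistic vascular model.

## Skeleton morphometry

`binarize()` uses Otsu's threshold by default (the field's usual choice when
no method is specified); a fixed threshold is available for strict
cross-image reproducibility. `skeletonize_mask()` applies Zhang–Suen
thinning followed by a sequential reduction that deletes 8-simple,
non-endpoint pixels until none remain — this removes the two-pixel
staircases Zhang–Suen leaves on diagonals, which would otherwise read as
junction chains.

Thinning algorithms are not intrinsically symmetric under image rotation, so
we make orientation-independence a design guarantee: the mask is first
mapped to a canonical orientation (the lexicographically minimal of its
eight axis-aligned rotations/reflections), thinned there, and mapped back.
Graph extraction itself (neighbor counts, junction clustering, step lengths)
is manifestly symmetric, so junction counts and total length are *exactly*
invariant under 90° rotations and flips.

Conventions worth stating because the literature rarely does:

* **Junction** = maximal 8-connected cluster of skeleton pixels with ≥ 3
  skeleton neighbors, counted once per cluster, so a crossing displayed as
  one dot is one junction.
* **Length** = inter-pixel step counting: each orthogonal step contributes
  1 px and each diagonal step √2 px, times the physical pixel size. An
  N-pixel straight path has length N−1 px. Staircase quantization biases
  lengths of oblique vessels upward by a few percent; ground-truth recovery
  stays within ±10%.
* Metrics inside an ROI count a junction when its representative pixel lies
  in the ROI and a step when both its pixels do.

## Local connected fractal dimension

At each sampled foreground pixel the foreground restricted to the largest
sampling box (default 31×31 px) is flood-filled from the pixel, and the
*connected* mass `mu(eps)` is counted inside concentric boxes of sides
`eps = 3, 5, …, 31`. The LFD is the least-squares slope of `ln mu` against
`ln eps`: exactly 1 for a straight line, exactly 2 for a filled region, and
log 3/log 2 ≈ 1.585 on average over a Sierpinski triangle (verified against
an independent global box-counting oracle in the tests). Restricting mass to
the locally *connected* set means parallel but unconnected neighbors do not
inflate a vessel's complexity — only branching does.

Tunable parameters (all logged in the returned objects):

* `box_sizes_px` (odd, default 3–31) and `stride_px` (default 4 for
  whole-image maps): a 31 px window at 20 um/px spans 620 um, comparable to
  the neighborhood a branching cortical vessel occupies.
* `min_scales_for_fit = 3`: pixels whose component yields fewer distinct
  masses are flagged invalid rather than fitted.
* Slopes are clipped to `[0, 2.2]` and clips are counted
  (`n_clipped`).

Histogram features use bins of width 0.01 over `[0, 2.2]`, normalized to sum
to 1. The modal bin is located on a lightly smoothed histogram (triangular
kernel over 5 bins) because the raw fine-binned argmax jitters by a few bins
under foreground subsampling; the *reported* `peak_frequency` is still the
raw relative frequency at that bin, preserving the interpretation of the
peak amplitude as a proxy for the number of vascular elements at the
dominant complexity. Skewness and kurtosis are population moments of the
underlying LFD samples (not of binned frequencies), and kurtosis is *excess*
kurtosis (normal = 0); with fewer than two occupied bins the moment fields
are returned as `NA` and flagged. `fractal_features()` therefore takes the
LFD map rather than a pre-binned histogram.

Under the default injury (global 0.3 + focal 0.9), the LFD histogram shifts
left, and peak frequency, skewness, and kurtosis all decrease relative to
the unablated network — the package's directional reproduction of the
injury phenotype, asserted over replicate cohorts in the test suite.

## Analysis regions

`concentric_rings()` builds ring 1 as the disk of the first radius and ring
k > 1 as the annulus between consecutive radii (exclusive inner, inclusive
outer), so rings are disjoint and per-ring metrics are never double-counted.
Radii convert from millimeters by `radius_mm * 1000 / pixel_size_um`,
rounded half-up. Rings are clipped to the cortex mask and the fraction of
the ideal ring area lost to clipping is always reported, so either
convention (clipped or unclipped) is reproducible downstream.
`hemisphere_masks()` splits at a midline column (assigned to neither side);
`mirror_mask()` reflects an ROI across the midline for contralateral
comparisons and is an exact involution for in-bounds regions.

## MR volumes: HRS and SWI

`generate_mr_phantom()` builds an ellipsoidal brain over background with a
hyperintense spherical-cap lesion seated at the cortical surface and an
optional hypointense hemorrhage core inside it. Lesion and hemorrhage sizes
are *realized by construction*: the sphere radius is chosen as the k-th
smallest distance so the compartment hits the requested fraction of brain
voxels up to discretization. The hemorrhage carries negative phase (default
−2 rad) in the companion phase volume.

`hrs_segment()` restricts the volume to the brain mask, rescales to
[0, 255], and recursively splits each region at the valley between the two
tallest modes of its smoothed intensity histogram (256 bins, moving average
of 5, modes at least 30 rescaled units apart; a flat valley splits at its
middle). Recursion stops on uniformity (coefficient of variation of the
*rescaled* values ≤ 0.02 — computed on the rescaled scale so that the whole
procedure is exactly equivariant under constant intensity shifts), on
regions smaller than 50 voxels, on unimodal histograms, or at depth 6.
Terminal intensity classes are then split into 6-connected 3D components,
and all reported means and split values are mapped back to original units.
`extract_lesion()` selects leaves whose mean lies within `mean_tolerance` of
an a-priori `mean_target` — these constants are unpublished for the original
method, so our defaults are phantom-calibrated and fully logged. Skull
stripping is replaced by the supplied brain mask (phantoms carry their own);
`estimate_brain_mask()` provides a threshold-plus-largest-component fallback
for real data.

`swi_process()` implements homodyne phase filtering: each complex slice
(magnitude × e^{i·phase}) is divided by its low-pass version obtained by
windowing central k-space with a separable raised-cosine of full width 48
voxels. The window is symmetric about the DC sample so that a real image has
an exactly real low-pass — hence zero phase leaves the magnitude untouched
to machine precision. The negative-phase mask `f(phi) = (phi + pi)/pi` for
`phi < 0` (1 otherwise) is multiplied into the magnitude four times; a voxel
at phase −pi/2 is attenuated to 0.5^4 = 6.25% of its magnitude.
`hanning_size = 0` bypasses the filter, exposing the closed-form mask
behavior directly. For hemorrhage extraction from SWI we select leaves
within 40 intensity units above the darkest leaf: the fourth-power mask
pushes hemorrhage below ~15% of brain intensity, while partial-phase
boundary voxels land in between; the window was calibrated on phantoms
(Dice ≈ 0.9).

## Statistics and reporting

`percent_reduction()` is `100 × (control − treated)/control`, returned at
full precision and formatted to one decimal in reports. `group_compare()`
defaults to Welch's t-test — the safer choice at n = 5–6 per group — with
the pooled Student variant available (`var_equal = TRUE`); ANOVA designs add
Bonferroni-adjusted pairwise tests (p × number of comparisons, capped at 1).
Correlations are plain Pearson r² with two-sided p; a repeated-measures
sphericity correction is sometimes named in this context in the literature,
but it does not apply to a simple bivariate correlation, so none is used.
`build_report()` emits group means ± SEM and effect tables per metric ×
region, flags significance at p < 0.05, marks effects not computable when a
group has n < 2, and serializes deterministically (no timestamps), so
regenerating from the same inputs is byte-identical.

## Orchestration and problem sizes

`run_experiment()` runs the whole design: per subject, generate → (TBI only)
ablate → rasterize → binarize → skeleton metrics + LFD features for the
whole image, hemispheres, and rings → group report. Every per-subject seed
derives from one master seed. A thin command-line wrapper
(`inst/scripts/vesselfract`, subcommands `simulate`, `analyze`, `fractal`,
`rings`, `mri`, `stats`, `run-all`) exposes each stage with `--config`,
`--seed`, and `--out` flags and exits nonzero with a JSON error object on
failure.

The test suite and the acceptance script run cohorts of 5 + 5 subjects at
the full 768² image size and use 256² networks (16 trunks) for replicated
property checks (20 seeds), which keeps a full run within a few minutes on
one CPU while leaving every assertion statistically comfortable.

## Known limitations

* The generator's branching geometry is calibrated for measurement
  sensitivity, not hemodynamic realism; absolute junction counts and
  lengths are not comparable to animal data, only directions and ratios.
* LFD values depend on the chosen scale range; comparisons are only valid
  within a fixed `fractal_config()`.
* Oblique-vessel length carries a small positive staircase bias inherent to
  8-connected step counting.
* HRS assumes compartments separate as histogram modes; overlapping
  intensity distributions (e.g., subtle edema) merge into one leaf.
* The SWI pipeline models phase as a compartment property plus noise; it
  does not simulate dipole fields, so "blooming" overestimation of
  hemorrhage volume is absent.
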