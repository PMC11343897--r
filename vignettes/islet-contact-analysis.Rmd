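---
title: "Quantifying beta-cell-capillary contacts, polarity and granule fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying beta-cell-capillary contacts, polarity and granule fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pancreatic beta cells live threaded through a dense capillary bed. Each
cell touches the vasculature at zero, one or — for roughly a third of mouse
beta cells — two separate contact points, and those contacts organise the
cell: a basal (capillary-facing) membrane domain enriched in adhesion and
presynaptic-scaffold proteins, a lateral domain against neighbouring cells,
and an apical domain facing luminal spaces. Insulin granule fusion is
targeted to the capillary contacts, and the total contact area per cell
scales with how much that cell secretes. In the db/db model of type 2
diabetes the capillaries widen and simplify: total capillary volume per
islet volume is unchanged while surface area — and with it per-cell contact
area and the two-contact population — falls.

`isletcap` implements the quantitative image analysis behind these
observations as a tested pipeline: 3D morphometrics of the capillary bed
and per-cell contact patches, membrane linescan polarity quantification,
automated fusion-event detection in extracellular-dye movies, and the
event–geometry statistics. Because the imaging volumes such a study rests
on are too large to ship and are in any case unavailable, the package
carries a synthetic-microscopy generator whose ground truth validates
every stage.

## The synthetic islet

`generate_capillary_network()` builds capillary tubes around smoothed
random-walk centerlines that traverse the volume (`tortuosity` is the
angular SD per 0.5 µm step; 0 gives straight tubes). `pack_cells()`
tessellates the remaining space into contiguous cells by seeded geodesic
region growing, adds a ~1 µm capsule shell at the volume boundary, and
carves thin (0.4 µm) luminal canaliculi along junctions where three or more
cells meet away from the vessels — these are the apical spaces of the real
tissue. Ground-truth contact patches are computed from the true labels with
the same `cell_contact_patches()` used on segmented data.

Default study conditions, chosen once to match the imaged system: 0.255 µm
isotropic voxels (the confocal z-step for mouse tissue; 0.336 µm available
for the human setting), 40 µm volumes for routine work, mean cell diameter
10 µm, eight tubes of radius 1.5–2.5 µm giving a capillary volume fraction
near 10% and, emergently, a realistic split of zero/one/two-contact cells
(roughly 10/60/30% across seeds — not tuned, a consequence of the tube
density). The anisotropic Gaussian PSF (σ 0.15 µm laterally, 0.45 µm
axially) and Poisson–Gaussian noise are the standard confocal
approximation. Membrane marker paints extend 0.3 µm into the cell:
junctional and scaffold zones have finite depth, and a one-voxel sheet
would be washed out by the axial PSF.

What the generator does *not* emulate: real laminin texture, pericytes and
endothelial nuclei, slice drift, depth-dependent attenuation,
photobleaching, or dye flow. Tests passing on this generator therefore
demonstrate correctness of the measurement code under the stated optics
and noise model, not robustness to every real-world artefact.

`perturb_dbdb()` emulates the diabetic remodelling as the study describes
it: tube radii are dilated while the tube count is pruned and a small
iterative radial correction applied, so total capillary volume inside the
islet is preserved (within 5%, usually 2%) while surface area falls. Cells
are re-packed with the original seed and the ground truth recomputed.

## Morphometry

`surface_area()` estimates isosurface area by the projection method: each
exposed voxel face contributes its area times |n_k|, the axis component of
the local unit normal taken from the gradient of a one-voxel Gaussian
pre-smoothing of the mask. This is exact for planar interfaces (the
projection theorem) and within ~1.5% of 4πr² / 2πrL for spheres and
cylinders at the default voxel sizes, including anisotropic z; naive face
counting was rejected because it overestimates oblique surfaces by up to
~50%. Unlike a triangulated mesh, the estimator yields per-voxel area
weights that restrict cleanly to contact patches. Faces on the volume
boundary are not counted, so bodies clipped by the field of view contribute
no cap area.

`segment_capillaries()` replaces the manual vessel tracing of the original
workflow. Laminin stains the basement membrane *around* the lumen, so after
smoothing and a global Otsu threshold the lumen is recovered as the shallow
complement: connected components of the sub-threshold space whose maximum
distance to the stained shell stays below `tunnel_radius_max` (4 µm). A
lumen is nowhere deeper than its tube radius, whereas the cell-bed
complement is several cell radii deep; this criterion works even though
tubes leave the volume and are not closed cavities (an ordinary hole fill
fails there, and the stained capsule would otherwise enclose the whole
islet). A final outward dilation (`boundary_offset`, 0.55 µm) compensates
the inward spread of the blurred wall past the threshold; the default was
calibrated once against synthetic ground truth by driving the mean signed
boundary error to zero under the default optics, and is a parameter to
revisit for other stain/PSF combinations.

`cell_contact_patches()` takes each cell's surface voxels within
`contact_distance` (1 µm, the event-proximity convention) of the capillary
mask and groups them into connected patches — the unit in which contacts
are counted, deliberately *not* collapsed by capillary identity, since two
appositions to one looping vessel still count as two contacts. Two
stabilising rules matter in practice:

* `min_patch_area` (1 µm²) drops single-voxel noise patches;
* `merge_distance` (2 µm) fuses fragments of one cell's contact surface
  separated by less than a sub-cellular gap. Genuinely distinct contacts in
  the generated geometry are never closer than ~2.2 µm (measured across
  seeds before the default was fixed), so merging below 2 µm cannot join
  real pairs, while it keeps the count stable against sub-micron boundary
  noise in a segmented mask.

Patches are numbered in spatial scan order within each cell, *not* by
size: the "capillary 1"/"capillary 2" labels of a two-contact cell are
arbitrary, and a size-ranked numbering would make domain 1 systematically
the larger interface and manufacture a spurious capillary-1-vs-2
difference.

Per-cell contact is reported both as absolute area (µm²) and as percentage
of the cell surface, since either normalisation of "contact area per beta
cell" is defensible; the columns are named distinctly.

## Polarity

`partition_membrane()` assigns membrane voxels with precedence
capillary > apical > lateral: contact proximity overrides everything, and
touching open extracellular space marks a luminal surface even where the
voxel also touches a neighbouring cell. Analysis is restricted to z-planes
where the cell's cross-section exceeds 20% of its maximum — "multiple
z-planes" without cherry-picking edge slices. `linescan_domain_intensity()`
reproduces the two-stage average of the original measurement exactly:
per plane, the mean intensity over the domain path dilated in-plane to a
5-pixel width; then an unweighted mean over planes. The two-stage form is
kept rather than pooling voxels because the variance structure differs.
`percent_of_total()` expresses each domain as a percentage of the summed
domain means (so every cell/channel sums to 100), and `enrichment_test()`
runs the one-way ANOVA with Tukey HSD pairwise comparisons used for such
data. Channels are not background-subtracted by default; a flat
subtraction can be applied upstream if needed. Linescan width is taken in
pixels, with the physical pixel size carried by the volume calibration.

## Fusion-event detection

The detector automates what was originally manual frame screening plus
ROI confirmation:

1. **Candidates** (`detect_candidates()`): the temporal-difference stack is
   band-pass filtered (difference of Gaussians, centre σ 0.4 µm, surround
   3×) to match ~1 µm spots; static structure such as dye-filled vessels
   cancels in the difference. Each pixel's filtered series is standardised
   by its robust (MAD) SD, and candidates are local spatiotemporal maxima
   above `z_threshold` (5) at which the centre-smoothed difference itself
   is positive (this rejects the surround lobes of the band-pass filter).
   Sub-pixel positions come from an intensity-weighted centroid in a 1 µm
   window; temporal resolution is one frame.
2. **Confirmation** (`confirm_event()`): a 0.7 µm ROI trace must show a
   rise completed within 2 frames above a baseline taken as the median of
   the 12 frames (2 s) preceding the rise, and a decay to baseline + 20% of
   amplitude within 2–9 frames after the peak — faster is shot noise,
   slower is a dye-filled compartment. The decay time comes from a
   weighted log-linear fit of the post-peak decay (weights y², the standard
   linearisation of an exponential fit): a single noisy threshold crossing
   is biased at the slow end of the physiological decay range, whereas the
   fit uses the whole profile, as kymograph inspection does.
3. **Deduplication** (`deduplicate()`): detections closer than 1 µm *and*
   1 s merge transitively, keeping the largest amplitude; repeated fusion
   at one site at different times is kept, as it is real signal. The
   transitive-merge rule is this package's convention.

On default synthetic movies (flash amplitude ≈ 13× the per-pixel noise SD,
event densities well below 0.02 events/µm²/min) the detector achieves
recall and precision above 0.9 with ~0.1 µm RMS localisation and
single-frame timing.

## Event statistics

All statistics go through the standard base-R machinery:
`wilcox.test` (paired signed-rank for near-vs-far rates, exact for n ≤ 25
with zero differences dropped; unpaired for the one- vs two-contact density
comparison), `cor.test(method = "spearman")` with average-rank ties for the
per-contact temporal coupling of 60 s-binned counts (constant series are
reported missing, not zero), and `lm` for the events-on-area regression
fitted through all cells regardless of contact number. Conventions fixed
where the source procedure is silent: the near/far boundary is half-open
(exactly 1.0 µm is far); events assign to the contact with the nearest
in-plane patch pixels, ties to the lower contact id; far events are
excluded from per-contact coupling but included in per-cell totals. Time
bins are half-open `[k·60, (k+1)·60)`.

The glucose-tolerance staging rule (`ipgtt_stage()`) integrates the
glucose trace by the trapezoid rule and applies the published outer
thresholds (stage 1 below 1600 mmol/l×min, stage 4 above 2800); only those
two thresholds are anchored, so the interior band is split evenly at 2200
as an explicit convention.

## Numerical and testing choices

* All randomness flows from explicit seeds through a private RNG scope;
  identical seeds give bitwise-identical volumes, movies and outputs, which
  the test suite asserts end-to-end on the full pipeline.
* Voxel `i` (1-based) is centred at `(i - 0.5) * voxel_size`; all areas and
  volumes are in µm²/µm³.
* Flash decay constants are drawn uniformly on [0.34, 0.90] s so the
  95%-return time (3τ) spans 1–2.7 s, inside the 1–3 s flash signature and
  consistent with the 9-frame confirmation bound (ln 5 · τ · 6 ≤ 8.7
  frames).
* The movie generator applies its event rate per micrometre of in-plane
  contact interface per minute (a per-area rate across a nominal 1 µm
  optical section), which preserves the generative linearity between
  per-cell event totals and contact extent.
* Test problem sizes: routine tests use 30 µm islets (~35 cells); the
  validation islet for classification and polarity is 44 µm (~115 cells);
  detector performance aggregates three 2-minute movies; null calibrations
  use 1000 replicates and power/recovery checks 30–100 replicates. These
  sizes make the whole suite run in minutes while keeping every check at
  or above the sample sizes of the study design it validates (38 cells for
  the regression, 9 cells for the paired near/far test, 12 cells for
  polarity).

## Known limitations

* The segmentation's `boundary_offset` is calibrated to the default
  wall-thickness/PSF model; a different stain or optics needs
  recalibration against a suitable reference.
* The two-stage linescan average weights planes equally, as the original
  measurement does; cells spanning few planes therefore carry noisier
  domain means.
* Contact patches below `min_patch_area`, and fragments within
  `merge_distance`, are deliberate stabilisations; geometries whose true
  contacts are smaller than 1 µm² or closer than 2 µm violate their
  assumptions.
* The detector has no sub-frame timing and no motion correction, and
  overlapping flashes within 1 µm and 1 s merge into one event by design.
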