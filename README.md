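# isletcap

Quantitative image analysis of the interface between pancreatic beta cells
and the islet capillary network.

Beta cells sit threaded through a dense capillary bed, and each cell
touches the vasculature at zero, one or two separate contact points. Those
contacts organise the cell — a basal membrane domain at each capillary,
a lateral domain against neighbouring cells, an apical domain on luminal
spaces — and they are where insulin granules fuse: per-cell fusion totals
scale with total contact area. In diabetic (db/db) islets the capillaries
widen and simplify, leaving capillary volume per islet volume unchanged
while surface area, per-cell contact area and the two-contact population
all fall.

`isletcap` implements the measurements behind these observations as a
tested R pipeline, for microscopists and quantitative biologists working
with 3D confocal stacks and two-photon dye movies of islet tissue:

* **Morphometry** — capillary segmentation from a basement-membrane
  (laminin) channel; capillary volume fraction `V_cap / V_islet`;
  surface-area density `S_cap / V_islet` (µm²/µm³) via a projection
  isosurface estimator; per-cell contact patches with areas, counts and
  the 0 / 1 / 2+ contact classification.
* **Polarity** — membrane partition into capillary_1 / capillary_2 /
  lateral / apical domains, 5-pixel-wide linescan means on multiple
  z-planes, per-domain percentages of total (summing to 100), and the
  one-way ANOVA + Tukey enrichment test.
* **Exocytosis detection** — automated detection of ~1 µm fusion flashes
  in 6 frames/s extracellular-dye movies: matched band-pass candidate
  detection on the temporal-difference stack, 0.7 µm ROI confirmation of
  the one-frame rise and 3–9-frame decay signature, duplicate merging.
* **Event statistics** — event-to-capillary distances (near = < 1 µm),
  per-cell near/far rates per µm of capillary interface with the paired
  Wilcoxon signed-rank test, per-contact assignment, 60 s binning,
  Spearman coupling between contacts, difference profiles, the
  events-vs-contact-area OLS regression, per-area densities with the
  Mann–Whitney comparison, and IPGTT AUC staging (stage 1 < 1600,
  stage 4 > 2800 mmol/l × min).
* **Synthetic microscopy** — a generator for labelled islet volumes
  (tortuous capillary tubes, packed ~10 µm cells, capsule, luminal
  canaliculi), marker channels with domain-specific enrichment under an
  anisotropic PSF and Poisson–Gaussian noise, and fusion movies with full
  ground truth — the validation substrate for every stage, including a
  volume-preserving capillary dilation that reproduces the db/db
  remodelling pattern.

## Worked example

```r
library(isletcap)

g <- generate_capillary_network(volume_shape = c(118, 118, 118),  # 30 um cube
                                n_tubes = 5, seed = 7)
g <- pack_cells(g, seed = 3)
g
#> Synthetic islet geometry
#>   volume: 118 x 118 x 118 voxels (30.1 x 30.1 x 30.1 um)
#>   voxel size: 0.255 x 0.255 x 0.255 um
#>   capillary tubes: 5 (17.5% of volume)
#>   cells: 34
#>   ground-truth contact patches: 36

morphometry_report(g$labels, g$labels == 1L, g$islet_mask, g$voxel_size)
#> Islet morphometry report
#>   capillary volume fraction: 0.1976
#>   capillary surface-area density: 0.1588 um^2/um^3
#>   cells: 34; contact proportions: 0: 5.9%  1: 82.4%  2+: 11.8%

sim <- simulate_fusion_movie(g, plane_z = 15, duration_s = 120, seed = 11)
events <- detect_events(sim$movie)
k <- floor(15 / g$voxel_size[3]) + 1
events <- distance_to_capillary(events, g$labels[, , k] == 1L,
                                g$voxel_size[1])
sprintf("detected %d events, %d within 1 um of a capillary",
        nrow(events), sum(events$near))
#> "detected 15 events, 12 within 1 um of a capillary"

# a full 20-min recording (ground truth only) for the near/far statistics
sim20 <- simulate_fusion_movie(g, plane_z = 15, duration_s = 1200, seed = 12,
                               render_frames = FALSE)
truth <- distance_to_capillary(sim20$ground_truth$events,
                               g$labels[, , k] == 1L, g$voxel_size[1])
len <- sim20$ground_truth$contact_length
rates <- events_per_capillary_length(truth, len[len$contact_length_um > 0, ])
near_far_test(rates$near_rate, rates$far_rate)$p_value
#> 0.001953125
```

The morphometry report says that in this small synthetic islet capillaries
occupy 19.8% of islet volume with 0.159 µm² of vessel surface per µm³ of
tissue, and that 11.8% of its 34 cells touch two capillaries. The detector
recovered 15 fusion flashes from the 2-minute movie, 12 of them within 1 µm
of a vessel; over a 20-minute recording the per-cell fusion rate per µm of
capillary interface is significantly higher near the vessels than away from
them (paired Wilcoxon signed-rank, p = 0.002, 10 cells), the targeting
signature of capillary-directed secretion.

The end-to-end runner `run_pipeline(default_config(seed = 1), "out/")`
chains simulation, segmentation, morphometry, polarity, detection and
statistics, writing CSV/JSON artefacts, TIFF volumes and a manifest with
the resolved seed and a config hash; a YAML config (see `read_config()`)
overrides any default. A thin command-line wrapper is available at
`inst/scripts/isletcap-run`.

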