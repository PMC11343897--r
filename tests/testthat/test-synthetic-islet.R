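test_that("capillary network handles the empty case and refuses tiny volumes", {
  g <- generate_capillary_network(c(40, 40, 40), n_tubes = 0L, seed = 1)
  expect_false(any(g$labels == 1L))
  expect_length(g$centerlines, 0)
  expect_error(
    generate_capillary_network(c(8, 8, 8), voxel_size = c(0.255, 0.255, 0.255),
                               n_tubes = 1L, radius_range = c(3, 3), seed = 1),
    "too small"
  )
  expect_error(pack_cells(g, target_cell_diameter = 20, seed = 1),
               "larger than the domain")
})

test_that("a straight tube voxelises to the analytic cylinder volume", {
  g <- generate_capillary_network(round(c(16, 16, 25) / VS), voxel_size = VS,
                                  n_tubes = 1L, radius_range = c(3, 3),
                                  tortuosity = 0, seed = 4)
  n_cap <- sum(g$labels == 1L)
  len <- polyline_len <- sum(sqrt(rowSums(diff(g$centerlines[[1]])^2)))
  expected <- pi * 9 * len / prod(VS)
  expect_lt(abs(n_cap / expected - 1), 0.05)
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_capillary_network(c(60, 60, 60), n_tubes = 3L, seed = 12)
  b <- generate_capillary_network(c(60, 60, 60), n_tubes = 3L, seed = 12)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centerlines, b$centerlines)
  pa <- pack_cells(a, seed = 5)
  pb <- pack_cells(b, seed = 5)
  expect_identical(pa$labels, pb$labels)
  expect_identical(pa$contacts$area_um2, pb$contacts$area_um2)
})

test_that("packed geometry partitions the volume and keeps cells connected", {
  g <- small_islet()
  lab <- g$labels
  # every voxel carries exactly one label from the known set
  expect_true(all(lab %in% c(0L, 1L, 2L, g$cell_ids)))
  expect_identical(sum(lab == 0) + sum(lab == 1) + sum(lab == 2) +
                     sum(lab >= 10), length(lab))
  # each cell is one 6-connected component
  comp <- isletcap:::label_same_components(
    ifelse(lab >= 10L, lab, 0L))
  for (cid in g$cell_ids) {
    expect_length(unique(comp[lab == cid]), 1L)
  }
  # ground-truth contact areas are positive
  expect_true(all(g$contacts$area_um2 > 0))
})

test_that("without capillaries cells tile the islet with zero contacts", {
  g <- generate_capillary_network(round(c(22, 22, 22) / VS), voxel_size = VS,
                                  n_tubes = 0L, seed = 1)
  g <- pack_cells(g, seed = 2)
  expect_gt(length(g$cell_ids), 3)
  expect_identical(nrow(g$contacts), 0L)
  cc <- classify_contact_counts(g$contacts, g$cell_ids)
  expect_equal(unname(cc$proportions["0"]), 1)
})

test_that("a cell wedged between two parallel tubes has two ground-truth contacts", {
  labels <- two_tube_geometry()
  d <- dim(labels)
  # carve a 9 um cell centred between the tubes (gap is 5 um wide)
  ax <- function(n, dd) (seq_len(n) - 0.5) * dd
  R2 <- outer(outer((ax(d[1], VS[1]) - 10)^2, (ax(d[2], VS[2]) - 10)^2, "+"),
              (ax(d[3], VS[3]) - 10)^2, "+")
  cell <- R2 <= 4.5^2 & labels == 0L
  labels[cell] <- 10L
  patches <- cell_contact_patches(labels, labels == 1L, VS)
  expect_identical(nrow(patches), 2L)
  expect_identical(unique(patches$cell_id), 10L)
  expect_length(unique(patches$capillary_component_id), 2L)
})

test_that("more tubes do not decrease the share of multi-contact cells", {
  frac2 <- function(n_tubes) {
    mean(vapply(1:10, function(s) {
      g <- generate_capillary_network(round(c(24, 24, 24) / c(0.4, 0.4, 0.4)),
                                      voxel_size = c(0.4, 0.4, 0.4),
                                      n_tubes = n_tubes, seed = s)
      g <- pack_cells(g, seed = s + 50)
      cc <- classify_contact_counts(g$contacts, g$cell_ids)
      unname(cc$proportions["2+"] %||% 0)
    }, 0.0))
  }
  `%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
  expect_gte(frac2(6L), frac2(2L))
})

test_that("volume-preserving dilation reproduces the diabetic remodelling pattern", {
  g <- small_islet()
  expect_identical(perturb_dbdb(g, 1), g)
  gp <- perturb_dbdb(g, 2)
  vs <- g$voxel_size
  v0 <- sum(g$labels == 1L & g$islet_mask)
  v1 <- sum(gp$labels == 1L & gp$islet_mask)
  expect_lt(abs(v1 / v0 - 1), 0.05)
  sad0 <- surface_area(g$labels == 1L, vs) / sum(g$islet_mask)
  sad1 <- surface_area(gp$labels == 1L, vs) / sum(gp$islet_mask)
  expect_lt(sad1, sad0)
  area0 <- sum(g$contacts$area_um2) / length(g$cell_ids)
  area1 <- sum(gp$contacts$area_um2) / length(gp$cell_ids)
  expect_lt(area1, area0)
})

test_that("rendered channels honour enrichment, blur and determinism", {
  g <- small_islet()
  flat <- render_channels(
    g, list(m = marker_spec("m", "cytoplasm", enrichment = 1, baseline = 7)),
    noise_params = list(gaussian_sd = 0, poisson_scale = 0), seed = 1
  )
  expect_equal(max(abs(flat$m - 7)), 0, tolerance = 1e-10)

  spec <- list(lip = marker_spec("lip", "contact_patch", enrichment = 10))
  ch <- render_channels(g, spec,
                        noise_params = list(gaussian_sd = 0,
                                            poisson_scale = 0), seed = 1)
  masks <- isletcap:::domain_masks(g)
  in_mean <- mean(ch$lip[masks$contact_patch])
  out_mean <- mean(ch$lip[!masks$contact_patch])
  expect_gte(in_mean / out_mean, 5)

  ch2 <- render_channels(g, spec,
                         noise_params = list(gaussian_sd = 2,
                                             poisson_scale = 0.5), seed = 5)
  ch3 <- render_channels(g, spec,
                         noise_params = list(gaussian_sd = 2,
                                             poisson_scale = 0.5), seed = 5)
  expect_identical(ch2$lip, ch3$lip)
  expect_error(marker_spec("x", "nucleus"), "unknown localisation")
})

test_that("fusion movies respect rate, placement and flash kinetics", {
  g <- small_islet()
  quiet <- simulate_fusion_movie(g, 15, duration_s = 30, event_rate = 0,
                                 seed = 1)
  expect_identical(nrow(quiet$ground_truth$events), 0L)

  sim <- simulate_fusion_movie(g, 15, duration_s = 240, event_rate = 0.15,
                               near_fraction = 1, seed = 2,
                               render_frames = FALSE)
  expect_gt(nrow(sim$ground_truth$events), 0)
  expect_true(all(sim$ground_truth$events$near))
  # all true decay constants give 95%-return in 1-3 s
  expect_true(all(3 * sim$ground_truth$events$tau_s >= 1 - 1e-9))
  expect_true(all(3 * sim$ground_truth$events$tau_s <= 3 + 1e-9))

  expect_error(simulate_fusion_movie(g, 15, duration_s = -1), "positive")
  expect_error(simulate_fusion_movie(g, 15, event_rate = -1), ">= 0")
})

test_that("a single noiseless flash decays as its closed form predicts", {
  g <- small_islet()
  sim <- simulate_fusion_movie(
    g, 15, duration_s = 30, event_rate = 0.05, near_fraction = 1,
    flash_params = list(amplitude = 40, fwhm_um = 1.0,
                        tau_range = c(0.5, 0.5)),
    noise_params = list(gaussian_sd = 0, poisson_scale = 0), seed = 8
  )
  ev <- sim$ground_truth$events
  ev <- ev[ev$peak_frame >= 10 & ev$peak_frame <= 170 &
             ev$x_um > 1 & ev$x_um < 29 & ev$y_um > 1 & ev$y_um < 29, ,
           drop = FALSE]
  expect_gt(nrow(ev), 0)
  e <- ev[1, ]
  tr <- extract_roi_trace(sim$movie, e$x_um, e$y_um, 0.7)
  peak <- tr[e$peak_frame] - tr[e$peak_frame - 5]
  # ROI mean over a 0.7 um disc loses < 25% of the 1 um FWHM peak
  expect_gt(peak, 0.75 * e$amplitude)
  # exp(-9/ (0.5*6)) = 0.0498: back near baseline within 9 frames
  resid <- tr[e$peak_frame + 9] - tr[e$peak_frame - 5]
  expect_lte(resid, 0.05 * e$amplitude + 1e-6)
})

test_that("mean event counts scale with in-plane contact length", {
  g <- small_islet()
  len <- inplane_contact_length(g, 15)
  len <- len[len$contact_length_um > 0, ]
  skip_if(nrow(len) < 3)
  counts <- matrix(0, nrow(len), 50)
  for (r in 1:50) {
    sim <- simulate_fusion_movie(g, 15, duration_s = 120, event_rate = 0.3,
                                 seed = 1000 + r, render_frames = FALSE)
    ev <- sim$ground_truth$events
    counts[, r] <- vapply(len$cell_id,
                          function(cid) sum(ev$cell_id == cid), 0L)
  }
  mean_counts <- rowMeans(counts)
  expected <- 0.3 * len$contact_length_um * 2   # rate * length * minutes
  big <- expected >= 1   # relative tolerance meaningless at tiny means
  expect_true(all(abs(mean_counts[big] / expected[big] - 1) < 0.10 +
                    3 / sqrt(50 * expected[big])))
})
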