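test_that("surface area matches closed forms for spheres and cylinders", {
  vs <- c(0.255, 0.255, 0.255)
  sph <- make_ball(c(12, 12, 12), 10, c(24, 24, 24), vs)
  expect_lt(abs(surface_area(sph, vs) / (4 * pi * 100) - 1), 0.05)
  # smaller sphere
  sph5 <- make_ball(c(7, 7, 7), 5, c(14, 14, 14), vs)
  expect_lt(abs(surface_area(sph5, vs) / (4 * pi * 25) - 1), 0.05)
  # cylinder r = 5, L = 50 clipped at the volume faces: lateral area only
  cyl <- make_axial_cylinder(5, c(14, 14, 50), vs)
  expect_lt(abs(surface_area(cyl, vs) / (2 * pi * 5 * 50) - 1), 0.05)
  # anisotropic z (human z-step)
  vsa <- c(0.255, 0.255, 0.336)
  spha <- make_ball(c(12, 12, 12), 10, c(24, 24, 24), vsa)
  expect_lt(abs(surface_area(spha, vsa) / (4 * pi * 100) - 1), 0.05)
  # cylinder r = 3 with anisotropic z
  cyl3 <- make_axial_cylinder(3, c(10, 10, 30), vsa)
  L <- round(30 / vsa[3]) * vsa[3]
  expect_lt(abs(surface_area(cyl3, vsa) / (2 * pi * 3 * L) - 1), 0.05)
})

test_that("dilating a convex body strictly increases its surface area", {
  vs <- c(0.255, 0.255, 0.255)
  sph <- make_ball(c(8, 8, 8), 5, c(16, 16, 16), vs)
  dil <- distance_map(sph, vs) <= vs[1]
  expect_gt(surface_area(dil, vs), surface_area(sph, vs))
})

test_that("empty and degenerate masks are handled as specified", {
  vs <- c(0.5, 0.5, 0.5)
  empty <- array(FALSE, c(10, 10, 10))
  expect_warning(a <- surface_area(empty, vs), "empty")
  expect_identical(a, 0)
  islet <- array(TRUE, c(10, 10, 10))
  expect_error(capillary_volume_fraction(empty, array(FALSE, c(10, 10, 10))),
               "empty")
  expect_error(segment_capillaries(array(0, c(10, 10, 10)), islet, vs),
               "degenerate")
  expect_error(segment_capillaries(array(1, c(10, 10, 10)),
                                   array(FALSE, c(10, 10, 10)), vs),
               "empty")
})

test_that("volume fraction is exact on trivial and analytic cases", {
  vs <- c(0.255, 0.255, 0.255)
  islet <- array(TRUE, c(20, 20, 20))
  expect_identical(capillary_volume_fraction(islet, islet), 1)
  expect_identical(capillary_volume_fraction(array(FALSE, c(20, 20, 20)),
                                             islet), 0)
  cyl <- make_axial_cylinder(3, c(50, 50, 50), vs)
  vf <- capillary_volume_fraction(cyl, array(TRUE, dim(cyl)))
  expect_lt(abs(vf / (pi * 9 * 50 / 50^3) - 1), 0.02)
})

test_that("surface areas are scale-equivariant and volume fraction scale-free", {
  g <- small_islet()
  cap <- g$labels == 1L
  k <- 2
  a1 <- surface_area(cap, g$voxel_size)
  a2 <- surface_area(cap, k * g$voxel_size)
  expect_equal(a2 / a1, k^2, tolerance = 1e-10)
  expect_identical(capillary_volume_fraction(cap, g$islet_mask),
                   capillary_volume_fraction(cap, g$islet_mask))
})

test_that("segmentation recovers a noiseless rendered tube with high overlap", {
  vs <- c(0.255, 0.255, 0.255)
  g <- generate_capillary_network(round(c(20, 20, 30) / vs), voxel_size = vs,
                                  n_tubes = 1L, radius_range = c(3, 3),
                                  tortuosity = 0.1, seed = 2)
  g <- pack_cells(g, seed = 1)
  ch <- render_channels(g, noise_params = list(gaussian_sd = 0,
                                               poisson_scale = 0), seed = 1)
  seg <- segment_capillaries(ch$laminin, g$islet_mask, vs)
  tru <- g$labels == 1L & g$islet_mask
  jaccard <- sum(seg & tru) / sum(seg | tru)
  expect_gte(jaccard, 0.8)
})

test_that("every true capillary component is recovered under realistic noise", {
  g <- small_islet()
  ch <- small_channels()
  seg <- segment_capillaries(ch$laminin, g$islet_mask, g$voxel_size)
  tc <- label_components(g$labels == 1L & g$islet_mask, 26L)
  sc <- label_components(seg, 26L)
  for (comp in seq_len(max(tc))) {
    expect_true(any(sc[tc == comp] > 0))
  }
})

test_that("contact patches follow the constructed-geometry rules", {
  vs <- c(0.255, 0.255, 0.255)
  # isolated cell far from any capillary: no patches
  labels <- two_tube_geometry()
  d <- dim(labels)
  lab_iso <- array(0L, dim = d)
  lab_iso[make_ball(c(10, 10, 10), 4, c(20, 20, 20), vs)] <- 10L
  lab_iso[labels == 1L & lab_iso == 0L] <- 0L
  p0 <- cell_contact_patches(lab_iso, array(FALSE, d), vs)
  expect_identical(nrow(p0), 0L)
  expect_identical(nrow(attr(p0, "cell_surface")), 1L)

  # cell against one straight tube: one patch
  lab1 <- labels
  cell <- make_ball(c(9, 10, 10), 2.2, c(20, 20, 20), vs) & lab1 == 0L
  lab1[cell] <- 10L
  p1 <- cell_contact_patches(lab1, lab1 == 1L, vs)
  expect_identical(nrow(p1), 1L)

  # no cells at all: empty table
  p2 <- cell_contact_patches(array(0L, d), labels == 1L, vs)
  expect_identical(nrow(p2), 0L)
})

test_that("contacts are counted as patches, not capillary identities", {
  vs <- c(0.255, 0.255, 0.255)
  labels <- two_tube_geometry()
  d <- dim(labels)
  # bridge the two tubes far from the cell so they form one component
  ax <- function(n, dd) (seq_len(n) - 0.5) * dd
  X <- ax(d[1], vs[1]); Y <- ax(d[2], vs[2]); Z <- ax(d[3], vs[3])
  bridge <- outer(outer(X >= 5 & X <= 15, abs(Y - 10) <= 2, "&"),
                  abs(Z - 1.5) <= 1.5, "&")
  labels[bridge] <- 1L
  cell <- make_ball(c(10, 10, 12), 4.5, c(20, 20, 20), vs) & labels == 0L
  labels[cell] <- 10L
  expect_identical(max(label_components(labels == 1L, 26L)), 1L)
  patches <- cell_contact_patches(labels, labels == 1L, vs)
  expect_identical(nrow(patches), 2L)
  expect_identical(unique(patches$capillary_component_id), 1L)
})

test_that("contact-count classification summarises proportions correctly", {
  empty <- cell_contact_patches(array(0L, c(5, 5, 5)),
                                array(FALSE, c(5, 5, 5)), c(1, 1, 1))
  cc <- classify_contact_counts(empty, cell_ids = 10:14)
  expect_equal(unname(cc$proportions["0"]), 1)
  expect_equal(sum(cc$proportions), 1)

  fake <- data.frame(cell_id = c(10L, 10L, 11L),
                     patch_id = c(1L, 2L, 1L), area_um2 = c(5, 5, 5))
  cc2 <- classify_contact_counts(fake, cell_ids = 10:12)
  expect_identical(unname(cc2$counts), c(2L, 1L, 0L))
  expect_equal(unname(cc2$proportions), rep(1 / 3, 3))
})

test_that("morphometry report agrees with ground truth on the synthetic islet", {
  g <- small_islet()
  rep_truth <- morphometry_report(g$labels, g$labels == 1L, g$islet_mask,
                                  g$voxel_size)
  expect_gte(rep_truth$capillary_volume_fraction, 0)
  expect_lte(rep_truth$capillary_volume_fraction, 1)
  expect_identical(nrow(rep_truth$per_cell), length(g$cell_ids))
  # per-cell truth table equals the geometry's own ground truth
  cc <- classify_contact_counts(g$contacts, g$cell_ids)
  expect_identical(rep_truth$per_cell$n_contacts, unname(as.integer(cc$counts)))
  # contact area never exceeds the cell surface
  expect_true(all(rep_truth$per_cell$contact_area_um2 <=
                    rep_truth$per_cell$cell_surface_um2))
})
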