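two_contact_cells <- function(g) {
  tab <- table(g$contacts$cell_id)
  as.integer(names(tab)[tab == 2L])
}

test_that("percent-of-total follows the stated arithmetic", {
  expect_equal(unname(percent_of_total(c(a = 1, b = 1, c = 1, d = 1))),
               rep(25, 4))
  expect_equal(unname(percent_of_total(c(a = 10, b = 0, c = 0, d = 0))),
               c(100, 0, 0, 0))
  expect_equal(unname(percent_of_total(c(a = 3, b = 1, c = 1, d = 0))),
               c(60, 20, 20, 0))
  # zero total or a single present domain is undefined, not zero
  expect_true(all(is.na(percent_of_total(c(a = 0, b = 0)))))
  expect_true(all(is.na(percent_of_total(c(a = 5, b = NA)))))
})

test_that("membrane partition covers the membrane with disjoint domains", {
  g <- small_islet()
  cids <- two_contact_cells(g)
  expect_gte(length(cids), 3)
  cid <- cids[1]
  part <- partition_membrane(g$labels, g$labels == 1L, g$contacts, cid,
                             g$voxel_size)
  expect_setequal(names(part$domains),
                  c("capillary_1", "capillary_2", "apical", "lateral"))
  lens <- lengths(part$domains)
  expect_true(all(lens > 0))
  all_vox <- unlist(part$domains)
  expect_identical(anyDuplicated(all_vox), 0L)
  # domains are membrane voxels of this cell on the analysed planes
  membrane <- isletcap:::boundary_mask(g$labels) & g$labels == cid
  expect_true(all(membrane[all_vox]))
  expect_error(partition_membrane(g$labels, g$labels == 1L, g$contacts,
                                  99999L, g$voxel_size), "unknown cell_id")
})

test_that("a cell fully surrounded by other cells has only lateral membrane", {
  d <- c(40, 40, 40)
  labels <- array(11L, dim = d)
  labels[15:25, 15:25, 15:25] <- 10L
  patches <- cell_contact_patches(labels, array(FALSE, d), c(0.5, 0.5, 0.5))
  part <- partition_membrane(labels, array(FALSE, d), patches, 10L,
                             c(0.5, 0.5, 0.5))
  expect_length(part$domains$apical, 0)
  expect_gt(length(part$domains$lateral), 0)
})

test_that("membrane touching open space is apical even when it also touches a cell", {
  d <- c(30, 30, 30)
  labels <- array(11L, dim = d)
  labels[10:20, 10:20, 10:20] <- 10L
  labels[21:30, , ] <- 0L   # open extracellular space on one side
  patches <- cell_contact_patches(labels, array(FALSE, d), c(0.5, 0.5, 0.5))
  part <- partition_membrane(labels, array(FALSE, d), patches, 10L,
                             c(0.5, 0.5, 0.5))
  ijk <- isletcap:::index_to_ijk(part$domains$apical, d)
  expect_true(all(ijk[, 1] == 20))   # the face against the open space
  # corner voxels of that face touch both another cell and background:
  # the precedence rule sends them to apical, so lateral excludes face 20
  ijk_lat <- isletcap:::index_to_ijk(part$domains$lateral, d)
  expect_true(all(ijk_lat[, 1] < 20))
})

test_that("linescan means reproduce constant and path-painted channels", {
  g <- small_islet()
  cid <- two_contact_cells(g)[1]
  part <- partition_membrane(g$labels, g$labels == 1L, g$contacts, cid,
                             g$voxel_size)
  const <- array(3.7, dim = dim(g$labels))
  m <- linescan_domain_intensity(const, part, width_px = 5)
  expect_equal(unname(m), rep(3.7, length(m)))
  # paint only the capillary_1 path; width-1 linescan sees exactly it
  painted <- array(0, dim = dim(g$labels))
  painted[part$domains$capillary_1] <- 10
  m1 <- linescan_domain_intensity(painted, part, width_px = 1)
  expect_equal(unname(m1["capillary_1"]), 10)
  expect_equal(unname(m1["lateral"]), 0)
  expect_equal(unname(m1["apical"]), 0)
  expect_error(linescan_domain_intensity(const, part, width_px = 4), "odd")
})

test_that("swapping the two capillary patches permutes the output symmetrically", {
  g <- small_islet()
  ch <- small_channels()
  cid <- two_contact_cells(g)[1]
  patches <- g$contacts
  rows <- which(patches$cell_id == cid)
  swapped <- patches
  swapped$patch_id[rows] <- rev(swapped$patch_id[rows])
  p1 <- partition_membrane(g$labels, g$labels == 1L, patches, cid,
                           g$voxel_size)
  p2 <- partition_membrane(g$labels, g$labels == 1L, swapped, cid,
                           g$voxel_size)
  m1 <- linescan_domain_intensity(ch$liprin, p1)
  m2 <- linescan_domain_intensity(ch$liprin, p2)
  expect_equal(m1[["capillary_1"]], m2[["capillary_2"]])
  expect_equal(m1[["capillary_2"]], m2[["capillary_1"]])
  expect_equal(m1[["lateral"]], m2[["lateral"]])
})

test_that("percentages sum to 100 for every cell and channel", {
  g <- small_islet()
  ch <- small_channels()
  prof <- cell_polarity_profiles(g, ch[c("dlg", "liprin")],
                                 cell_ids = two_contact_cells(g))
  sums <- tapply(prof$percent, interaction(prof$cell_id, prof$channel),
                 sum, na.rm = TRUE)
  expect_true(all(abs(sums - 100) < 0.01))
})

test_that("uniform and contact-enriched markers show their expected patterns", {
  g <- small_islet()
  ch <- small_channels()
  cids <- two_contact_cells(g)
  prof <- cell_polarity_profiles(g, ch[c("dlg", "liprin")], cell_ids = cids)

  # membrane-uniform marker: no domain far from 100/4
  dlg <- prof[prof$channel == "dlg", ]
  mp <- tapply(dlg$percent, dlg$domain, mean, na.rm = TRUE)
  se <- tapply(dlg$percent, dlg$domain, function(x) {
    sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  })
  expect_true(all(abs(mp - 25) < pmax(3 * se, 3)))

  # contact-enriched marker: both capillary domains exceed lateral + apical
  lip <- prof[prof$channel == "liprin", ]
  ml <- tapply(lip$percent, lip$domain, mean, na.rm = TRUE)
  expect_gt(ml[["capillary_1"]], ml[["lateral"]])
  expect_gt(ml[["capillary_1"]], ml[["apical"]])
  expect_gt(ml[["capillary_2"]], ml[["lateral"]])
  expect_gt(ml[["capillary_2"]], ml[["apical"]])
})

test_that("intensity ratio recovers the painted enrichment without noise", {
  g <- small_islet()
  spec <- list(m = marker_spec("m", "contact_patch", enrichment = 6))
  ch <- render_channels(g, spec, psf_sigma_um = c(0.05, 0.05, 0.05),
                        noise_params = list(gaussian_sd = 0,
                                            poisson_scale = 0), seed = 1)
  cid <- two_contact_cells(g)[1]
  part <- partition_membrane(g$labels, g$labels == 1L, g$contacts, cid,
                             g$voxel_size)
  m <- linescan_domain_intensity(ch$m, part, width_px = 1)
  ratio <- mean(m[c("capillary_1", "capillary_2")]) / m[["lateral"]]
  expect_lt(abs(ratio / 6 - 1), 0.2)
})

test_that("enrichment test separates domains and handles degenerate input", {
  sep <- data.frame(domain = rep(c("a", "b"), each = 3),
                    percent = c(0, 0.1, -0.1, 100, 99.9, 100.1))
  r <- enrichment_test(sep)
  expect_lt(r$p_value, 0.001)
  flat <- data.frame(domain = rep(c("a", "b"), each = 3), percent = 50)
  r2 <- enrichment_test(flat)
  expect_identical(r2$p_value, 1)
  expect_warning(
    enrichment_test(data.frame(domain = c("a", "a", "a", "b", "b", "c"),
                               percent = c(1, 2, 3, 4, 5, 6))),
    "excluding"
  )
  expect_error(suppressWarnings(
    enrichment_test(data.frame(domain = "a", percent = 1))
  ), ">=2 domains")
})

test_that("a 12-cell contact-enriched channel reproduces the enrichment statistics", {
  g <- small_islet()
  ch <- small_channels()
  cids <- head(two_contact_cells(g), 12)
  prof <- cell_polarity_profiles(g, ch["liprin"], cell_ids = cids)
  r <- enrichment_test(prof)
  expect_lt(r$p_value, 0.001)
  pw <- r$pairwise
  cap_vs_lat <- pw$p_adj[pw$comparison %in%
                           c("lateral-capillary_1", "capillary_1-lateral")]
  cap12 <- pw$p_adj[pw$comparison %in%
                      c("capillary_2-capillary_1", "capillary_1-capillary_2")]
  expect_lt(cap_vs_lat, 0.05)
  expect_gt(cap12, 0.05)
})
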