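test_that("event-to-capillary distances use the half-open near convention", {
  mask <- matrix(FALSE, 60, 40)
  mask[1:10, ] <- TRUE          # straight boundary at x = 2 um (px 0.2)
  px <- 0.2
  ev <- data.frame(x_um = c(1.0, 5.0, 2.7, 3.1), y_um = c(4, 4, 4, 4))
  out <- distance_to_capillary(ev, mask, px)
  expect_identical(out$capillary_distance_um[1], 0)      # inside the vessel
  expect_true(out$near[1])
  expect_lt(abs(out$capillary_distance_um[2] - 3.0), px + 1e-9)
  expect_false(out$near[2])
  expect_true(out$near[3])                               # just under 1 um
  expect_false(out$near[4])                              # >= 1 um is far
  # exact tie at 1.0 um: pixel centres make this exactly 1.0
  tie <- data.frame(x_um = 2.85, y_um = 4)  # falls in the pixel centred 2.9
  d_tie <- distance_to_capillary(tie, mask, px)
  expect_equal(d_tie$capillary_distance_um, 1.0, tolerance = 1e-12)
  expect_false(d_tie$near)

  expect_warning(
    inf <- distance_to_capillary(ev, matrix(FALSE, 10, 10), px),
    "no capillary"
  )
  expect_true(all(is.infinite(inf$capillary_distance_um)))
})

test_that("per-length rates do the stated arithmetic and drop zero lengths", {
  ev <- data.frame(cell_id = c(10L, 10L, 10L, 10L, 10L, 11L),
                   near = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  len <- data.frame(cell_id = c(10L, 11L, 12L),
                    contact_length_um = c(10, 4, 0))
  expect_warning(r <- events_per_capillary_length(ev, len), "zero interface")
  expect_identical(nrow(r), 2L)
  expect_equal(r$near_rate[r$cell_id == 10], 0.5)
  expect_equal(r$far_rate[r$cell_id == 10], 0)
  expect_equal(r$near_rate[r$cell_id == 11], 0)
  expect_equal(r$far_rate[r$cell_id == 11], 0.25)
})

test_that("the paired signed-rank test matches its exact distribution", {
  # 9 pairs, all one-signed: two-sided exact p = 2 / 2^9
  near <- 1:9
  far <- rep(0, 9)
  r <- near_far_test(near, far)
  expect_equal(r$p_value, 2 / 2^9, tolerance = 1e-12)
  expect_identical(r$n_pairs, 9L)
  # all-zero differences: missing
  r0 <- near_far_test(rep(1, 5), rep(1, 5))
  expect_true(is.na(r0$p_value))
})

test_that("the signed-rank null rejects at its nominal level", {
  set.seed(101)
  rej <- mean(replicate(400, {
    a <- rnorm(12); b <- rnorm(12)
    near_far_test(a, b)$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("event assignment picks the nearest contact with a low-id tie-break", {
  cp <- list(
    "1" = cbind(c(0, 0), c(0, 1)),
    "2" = cbind(c(10, 10), c(0, 1))
  )
  ev <- data.frame(x_um = c(1, 9, 5), y_um = c(0, 0, 0),
                   near = c(TRUE, TRUE, TRUE))
  out <- assign_to_contact(ev, cp)
  expect_identical(out$contact_id, c("1", "2", "1"))   # 5 is equidistant
  # far events stay unassigned
  ev2 <- data.frame(x_um = 1, y_um = 0, near = FALSE)
  expect_true(is.na(assign_to_contact(ev2, cp)$contact_id))
  # single contact takes every near event
  out3 <- assign_to_contact(ev, cp["1"])
  expect_true(all(out3$contact_id == "1"))
  expect_error(assign_to_contact(ev, list()), "no contacts")
})

test_that("binning is half-open with conserved totals", {
  expect_identical(bin_events(numeric(0)), rep(0L, 20))
  b <- bin_events(c(0, 59.9, 60.0, 1199.9))
  expect_identical(b[1], 2L)
  expect_identical(b[2], 1L)
  expect_identical(b[20], 1L)
  expect_identical(sum(b), 4L)
  expect_error(bin_events(1200), "\\[0, duration\\)")
  expect_error(bin_events(-1), "\\[0, duration\\)")
})

test_that("contact coupling recovers exact correlations and reports constants", {
  s <- c(3, 1, 4, 1, 5, 9, 2, 6)
  r <- contact_coupling(s, s)
  expect_equal(r$r_s, 1)
  r2 <- contact_coupling(s, -s)
  expect_equal(r2$r_s, -1)
  rc <- contact_coupling(rep(2, 8), s)
  expect_true(is.na(rc$r_s))
  expect_match(rc$reason, "constant")
  expect_error(contact_coupling(1:3, 1:3), ">= 5 bins")
})

test_that("the coupling null is centred with nominal rejection", {
  set.seed(77)
  res <- replicate(600, {
    a <- rpois(20, 3); b <- rpois(20, 3)
    cc <- contact_coupling(a, b)
    c(cc$r_s, cc$p_value)
  })
  ok <- !is.na(res[1, ])
  expect_lt(abs(mean(res[1, ok])), 0.05)
  expect_lt(abs(mean(res[2, ok] < 0.05) - 0.05), 0.025)
})

test_that("difference profiles are plain absolute differences", {
  expect_identical(difference_profile(c(3, 0, 2), c(0, 3, 2)), c(3, 3, 0))
  expect_identical(difference_profile(1:5, 1:5), rep(0L, 5))
})

test_that("an early-divergent generator peaks the mean difference profile early", {
  set.seed(9)
  profs <- replicate(40, {
    # contacts phase-shifted in the first 5 bins, synchronous afterwards
    a <- c(rpois(5, 6), rpois(15, 3))
    b <- c(rpois(5, 1), rpois(15, 3))
    difference_profile(a, b)
  })
  mp <- rowMeans(profs)
  expect_gt(mean(mp[1:5]), mean(mp[6:20]))
})

test_that("events-vs-area regression recovers exact and noisy slopes", {
  area <- c(10, 20, 30, 40)
  fit <- suppressWarnings(events_vs_area_regression(0.5 * area, area))
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(events_vs_area_regression(c(1, 2, 3), c(5, 5, 5)),
               "degenerate")
  expect_error(events_vs_area_regression(1:2, 1:2), ">= 3 cells")
  expect_error(events_vs_area_regression(1:3, c(-1, 2, 3)), "positive")

  # permuting the pairing destroys the fit
  set.seed(3)
  areas <- runif(38, 5, 60)
  counts <- rpois(38, 0.7 * areas)
  r2_true <- events_vs_area_regression(counts, areas)$r_squared
  r2_perm <- mean(replicate(30, {
    events_vs_area_regression(sample(counts), areas)$r_squared
  }))
  expect_gt(r2_true, 3 * r2_perm)
})

test_that("per-area densities equalise constructed one- and two-contact groups", {
  expect_equal(events_per_area(10, 20, 1)$density, 0.5)
  one_area <- runif(15, 10, 30)
  one_counts <- rpois(15, 0.5 * one_area)
  two_area <- 2 * one_area
  two_counts <- rpois(15, 0.5 * two_area)
  r <- events_per_area(c(one_counts, two_counts), c(one_area, two_area),
                       c(rep(1, 15), rep(2, 15)))
  expect_gt(r$p_value, 0.001)   # same density distribution
  r_empty <- events_per_area(c(1, 2), c(5, 5), c(1, 1))
  expect_true(is.na(r_empty$p_value))
})

test_that("IPGTT staging applies the printed AUC thresholds", {
  t120 <- c(0, 30, 60, 90, 120)
  r1 <- ipgtt_stage(t120, rep(10, 5))
  expect_equal(r1$auc, 1200)
  expect_identical(r1$stage, 1L)
  r4 <- ipgtt_stage(t120, rep(25, 5))
  expect_equal(r4$auc, 3000)
  expect_identical(r4$stage, 4L)
  # trapezoid consistency: collinear midpoint changes nothing
  a2 <- ipgtt_stage(c(0, 120), c(10, 10))$auc
  a3 <- ipgtt_stage(c(0, 60, 120), c(10, 10, 10))$auc
  expect_identical(a2, a3)
  # interior band splits at 2200
  expect_identical(ipgtt_stage(t120, rep(15, 5))$stage, 2L)  # AUC 1800
  expect_identical(ipgtt_stage(t120, rep(20, 5))$stage, 3L)  # AUC 2400
  expect_error(ipgtt_stage(c(0, 60), c(-1, 5)), "negative")
  expect_error(ipgtt_stage(c(0, 0), c(5, 5)), "increasing")
  expect_error(ipgtt_stage(0, 5), ">= 2 time points")
})
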