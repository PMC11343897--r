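# Spatial and temporal statistics linking granule-fusion events to
# capillary-contact geometry: near/far targeting, per-contact assignment and
# temporal coupling, per-cell totals against contact area, and the glucose
# tolerance (IPGTT) staging rule.

#' Distance from events to the nearest capillary
#'
#' Euclidean distance (um) from each event position to the nearest capillary
#' pixel of the in-plane mask, via a distance transform; classifies events
#' as near (`< near_threshold`) or far (`>=`, half-open so a tie at exactly
#' the threshold is far).
#'
#' @param events data frame with `x_um`, `y_um`.
#' @param capillary_mask_2d logical matrix (in-plane capillary mask).
#' @param pixel_size pixel size (um).
#' @param near_threshold near/far boundary (um), default 1.
#' @return the events with `capillary_distance_um` and `near` columns; if
#'   the plane holds no capillary, distances are `Inf` with a warning.
#' @export
distance_to_capillary <- function(events, capillary_mask_2d, pixel_size,
                                  near_threshold = 1.0) {
  if (!any(capillary_mask_2d)) {
    warning("no capillary in plane: distances are infinite")
    events$capillary_distance_um <- Inf
    events$near <- FALSE
    return(events)
  }
  d2 <- dim(capillary_mask_2d)
  m3 <- array(capillary_mask_2d, dim = c(d2, 1L))
  dm <- array(cpp_edt3d(as.logical(m3), dim(m3),
                        c(pixel_size, pixel_size, 1)), dim = d2)
  i <- pmin(pmax(floor(events$x_um / pixel_size) + 1L, 1L), d2[1])
  j <- pmin(pmax(floor(events$y_um / pixel_size) + 1L, 1L), d2[2])
  events$capillary_distance_um <- dm[cbind(i, j)]
  events$near <- events$capillary_distance_um < near_threshold
  events
}

#' Per-cell event rates per length of capillary interface
#'
#' Near and far event counts normalised by the same cell's capillary
#' interface length, giving paired per-cell rates (events/um over the
#' recording).
#'
#' @param events data frame with `cell_id` and `near` columns.
#' @param contact_length data frame `cell_id`, `contact_length_um` (e.g.
#'   from [inplane_contact_length()]).
#' @return data frame `cell_id`, `n_near`, `n_far`, `length_um`,
#'   `near_rate`, `far_rate`; cells with zero interface length are excluded
#'   with a warning.
#' @export
events_per_capillary_length <- function(events, contact_length) {
  zero <- contact_length$contact_length_um <= 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero interface length excluded")
    contact_length <- contact_length[!zero, , drop = FALSE]
  }
  out <- contact_length[, c("cell_id", "contact_length_um")]
  names(out)[2] <- "length_um"
  out$n_near <- vapply(out$cell_id, function(cid) {
    sum(events$cell_id == cid & events$near)
  }, 0L)
  out$n_far <- vapply(out$cell_id, function(cid) {
    sum(events$cell_id == cid & !events$near)
  }, 0L)
  out$near_rate <- out$n_near / out$length_um
  out$far_rate <- out$n_far / out$length_um
  out[, c("cell_id", "n_near", "n_far", "length_um", "near_rate",
          "far_rate")]
}

#' Paired Wilcoxon signed-rank test of near vs far rates
#'
#' Two-sided Wilcoxon matched-pairs signed-rank test on per-cell near minus
#' far rates. Zero differences are dropped (the standard signed-rank
#' convention); the exact distribution is used for n <= 25 when the
#' magnitudes are untied.
#'
#' @param near_rate,far_rate paired per-cell rates.
#' @return list `p_value`, `n_pairs` (non-zero pairs), `statistic`;
#'   `p_value` is `NA` when every pair is tied.
#' @export
near_far_test <- function(near_rate, far_rate) {
  stopifnot(length(near_rate) == length(far_rate))
  d <- near_rate - far_rate
  d <- d[d != 0]
  if (length(d) == 0L) {
    return(list(p_value = NA_real_, n_pairs = 0L, statistic = NA_real_))
  }
  wt <- suppressWarnings(
    wilcox.test(d, exact = length(d) <= 25)
  )
  list(p_value = wt$p.value, n_pairs = length(d),
       statistic = unname(wt$statistic))
}

#' Assign near events to contact patches
#'
#' Each near event is assigned to the contact whose in-plane patch pixels
#' are nearest (deterministic tie-break towards the lower contact id); far
#' events stay unassigned (`NA`).
#'
#' @param events data frame with `x_um`, `y_um` and `near`.
#' @param contact_pixels named list: for each contact id, a matrix of patch
#'   pixel coordinates (columns `x_um`, `y_um`).
#' @return the events with a `contact_id` column.
#' @export
assign_to_contact <- function(events, contact_pixels) {
  if (length(contact_pixels) == 0L) {
    stop("cell has no contacts", call. = FALSE)
  }
  ids <- names(contact_pixels)
  ids <- ids[order(as.numeric(ids))]   # low-id tie-break
  events$contact_id <- NA_character_
  for (e in seq_len(nrow(events))) {
    if (!isTRUE(events$near[e])) next
    dmin <- vapply(ids, function(id) {
      px <- contact_pixels[[id]]
      min(sqrt((px[, 1] - events$x_um[e])^2 +
                 (px[, 2] - events$y_um[e])^2))
    }, 0.0)
    events$contact_id[e] <- ids[which.min(dmin)]   # first minimum = lower id
  }
  events
}

#' In-plane pixel coordinates of a cell's contact patches
#'
#' @param geometry a packed `islet_geometry`.
#' @param cell_id cell of interest.
#' @param plane_z plane position (um).
#' @param patches patch table; defaults to ground truth.
#' @return named list (by patch id) of coordinate matrices; patches without
#'   pixels in the plane fall back to their 3D centroid projection.
#' @export
contact_pixels_in_plane <- function(geometry, cell_id, plane_z,
                                    patches = NULL) {
  patches <- patches %||% geometry$contacts
  rows <- which(patches$cell_id == cell_id)
  vox_list <- attr(patches, "voxels")
  d <- dim(geometry$labels)
  vs <- geometry$voxel_size
  k <- floor(plane_z / vs[3]) + 1L
  out <- list()
  for (r in rows) {
    ijk <- index_to_ijk(vox_list[[r]], d)
    inplane <- ijk[, 3] == k
    xy <- if (any(inplane)) {
      cbind((ijk[inplane, 1] - 0.5) * vs[1], (ijk[inplane, 2] - 0.5) * vs[2])
    } else {
      matrix(c(patches$centroid_x[r], patches$centroid_y[r]), ncol = 2L)
    }
    out[[as.character(patches$patch_id[r])]] <- xy
  }
  out
}

#' Bin event times into fixed-width bins
#'
#' @param times event times in seconds, in `[0, duration)`.
#' @param duration recording duration (s), default the 20-min stimulation.
#' @param bin_width bin width (s), default 60.
#' @return integer vector of counts over half-open bins
#'   `[k*bin_width, (k+1)*bin_width)`.
#' @export
bin_events <- function(times, duration = 1200, bin_width = 60) {
  if (length(times) > 0 && (any(times < 0) || any(times >= duration))) {
    stop("event times must lie in [0, duration)", call. = FALSE)
  }
  n_bins <- ceiling(duration / bin_width)
  tabulate(floor(times / bin_width) + 1L, nbins = n_bins)
}

#' Temporal coupling between two contacts of one cell
#'
#' Spearman rank correlation (average ranks for ties, two-sided p) between
#' the binned event counts at two capillary contacts. Constant series make
#' the correlation undefined; it is reported missing with the reason.
#'
#' @param series_1,series_2 equal-length binned counts (>= 5 bins).
#' @return list `r_s`, `p_value`, `n_bins`, `reason`.
#' @export
contact_coupling <- function(series_1, series_2) {
  stopifnot(length(series_1) == length(series_2))
  if (length(series_1) < 5L) stop("need >= 5 bins", call. = FALSE)
  if (sd(series_1) == 0 || sd(series_2) == 0) {
    return(list(r_s = NA_real_, p_value = NA_real_,
                n_bins = length(series_1),
                reason = "constant series: correlation undefined"))
  }
  ct <- suppressWarnings(
    cor.test(series_1, series_2, method = "spearman", exact = FALSE)
  )
  list(r_s = unname(ct$estimate), p_value = ct$p.value,
       n_bins = length(series_1), reason = "ok")
}

#' Per-bin absolute difference between two contacts' event series
#'
#' @param series_1,series_2 equal-length binned counts.
#' @return numeric vector of per-bin `|difference|`; average profiles across
#'   cells by stacking results with `rowMeans`.
#' @export
difference_profile <- function(series_1, series_2) {
  stopifnot(length(series_1) == length(series_2))
  abs(series_1 - series_2)
}

#' Regression of per-cell event totals on contact area
#'
#' Ordinary least squares of total fusion events per cell on total capillary
#' contact area per cell, one line over all cells regardless of contact
#' number.
#'
#' @param events_per_cell numeric vector of per-cell totals.
#' @param areas_um2 per-cell total contact areas (um^2), all > 0.
#' @return list of class `events_area_fit`: `slope` (events/um^2),
#'   `intercept`, `r_squared`, `p_value`, `n_cells`, and the `lm` fit.
#' @export
events_vs_area_regression <- function(events_per_cell, areas_um2) {
  stopifnot(length(events_per_cell) == length(areas_um2))
  if (length(areas_um2) < 3L) stop("need >= 3 cells", call. = FALSE)
  if (any(areas_um2 <= 0)) stop("areas must be positive", call. = FALSE)
  if (sd(areas_um2) < 1e-12) {
    stop("degenerate regression: contact areas are constant", call. = FALSE)
  }
  fit <- lm(events_per_cell ~ areas_um2)
  sm <- summary(fit)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = sm$coefficients[2, "Pr(>|t|)"],
         n_cells = length(areas_um2), fit = fit),
    class = "events_area_fit"
  )
}

#' @export
print.events_area_fit <- function(x, ...) {
  cat(sprintf(
    "Events vs contact area: slope %.3f events/um^2, R^2 %.2f, p %.2g (n = %d cells)\n",
    x$slope, x$r_squared, x$p_value, x$n_cells))
  invisible(x)
}

#' Per-cell event density and one- vs two-contact comparison
#'
#' Events per square micrometre of contact area per cell, with a two-sided
#' Mann-Whitney test comparing one-contact and two-contact cells.
#'
#' @param events_per_cell per-cell totals.
#' @param areas_um2 per-cell contact areas (> 0).
#' @param n_contacts per-cell contact counts.
#' @return list: `density` (per cell), `p_value` (Mann-Whitney one- vs
#'   two-contact; `NA` when a group is empty), `n_one`, `n_two`.
#' @export
events_per_area <- function(events_per_cell, areas_um2, n_contacts) {
  stopifnot(all(areas_um2 > 0))
  density <- events_per_cell / areas_um2
  one <- density[n_contacts == 1]
  two <- density[n_contacts >= 2]
  p <- if (length(one) == 0L || length(two) == 0L) {
    NA_real_
  } else {
    suppressWarnings(wilcox.test(one, two)$p.value)
  }
  list(density = density, p_value = p, n_one = length(one),
       n_two = length(two))
}

#' Stage diabetes severity from an IPGTT glucose trace
#'
#' Trapezoidal area under the glucose-time curve (mmol/l x min) staged by
#' the compensation/severe-diabetes thresholds: stage 1 below 1600, stage 4
#' above 2800, with the intermediate band split evenly at 2200 into stages
#' 2 and 3 (the interior boundary is a convention; only the outer thresholds
#' are anchored).
#'
#' @param time_min time points (minutes), strictly increasing.
#' @param glucose_mmol glucose (mmol/l), non-negative.
#' @return list `auc` (mmol/l x min) and `stage` (1-4).
#' @export
ipgtt_stage <- function(time_min, glucose_mmol) {
  stopifnot(length(time_min) == length(glucose_mmol))
  if (length(time_min) < 2L) stop("need >= 2 time points", call. = FALSE)
  if (any(diff(time_min) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(glucose_mmol < 0)) {
    stop("negative glucose values", call. = FALSE)
  }
  n <- length(time_min)
  auc <- sum(diff(time_min) * (glucose_mmol[-1] + glucose_mmol[-n]) / 2)
  stage <- if (auc < 1600) 1L else if (auc < 2200) 2L else if (auc <= 2800) {
    3L
  } else 4L
  list(auc = auc, stage = stage)
}
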