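# Two-photon-style fusion movies: a single optical plane through the islet,
# extracellular dye filling the capillary lumen and interstitial spaces, and
# transient ~1 um granule-fusion flashes with one-frame rise and exponential
# decay, against Poisson-Gaussian noise. Ground truth is returned for every
# simulated event.

#' Per-cell capillary interface length in one optical plane
#'
#' Length of each cell's membrane lying within `near_threshold` of a
#' capillary in the given plane, estimated as boundary-pixel count times
#' pixel size. Used both to set generative event rates and to normalise
#' event frequencies per length of capillary.
#'
#' @param geometry a packed `islet_geometry`.
#' @param plane_z plane position in micrometres.
#' @param near_threshold apposition distance (um), default 1.
#' @return data frame `cell_id`, `contact_length_um`, `n_pixels`.
#' @export
inplane_contact_length <- function(geometry, plane_z, near_threshold = 1.0) {
  sl <- plane_slice(geometry, plane_z)
  near <- sl$membrane & sl$capdist < near_threshold
  ids <- sort(unique(sl$labels[sl$labels >= CELL_ID_START]))
  n <- vapply(ids, function(cid) sum(near & sl$labels == cid), 0L)
  data.frame(cell_id = ids, contact_length_um = n * sl$pixel_size,
             n_pixels = n)
}

# extract one z-plane with 2D membrane and capillary-distance maps
plane_slice <- function(geometry, plane_z) {
  d <- dim(geometry$labels)
  vs <- geometry$voxel_size
  k <- floor(plane_z / vs[3]) + 1L
  if (k < 1L || k > d[3]) {
    stop("plane_z does not intersect the volume", call. = FALSE)
  }
  lab <- geometry$labels[, , k]
  if (!any(lab >= CELL_ID_START) && !any(lab == LBL_CAP)) {
    stop("plane does not intersect the islet", call. = FALSE)
  }
  lab3 <- array(lab, dim = c(d[1], d[2], 1L))
  membrane <- array(cpp_boundary_mask(as.integer(lab3), dim(lab3)),
                    dim = c(d[1], d[2]))
  membrane <- membrane & lab >= CELL_ID_START
  capdist <- if (any(lab == LBL_CAP)) {
    array(cpp_edt3d(as.logical(lab3 == LBL_CAP), dim(lab3),
                    c(vs[1], vs[2], 1)), dim = c(d[1], d[2]))
  } else {
    array(Inf, dim = c(d[1], d[2]))
  }
  list(labels = lab, membrane = membrane, capdist = capdist,
       pixel_size = vs[1], k = k)
}

#' Simulate an extracellular-dye fusion movie
#'
#' Background dye fills the capillary lumen and interstitial spaces of the
#' chosen plane. Granule-fusion events are drawn per cell as a Poisson count
#' proportional to the cell's in-plane capillary interface length (constant
#' rate per unit contact, the generative assumption linking fusion totals to
#' contact area), placed on the membrane within 1 um of a capillary with
#' probability `near_fraction` and elsewhere on the membrane otherwise. Each
#' event is a circular Gaussian flash (FWHM ~1 um) with a single-frame rise
#' and exponential decay whose 95%-return time lies in 1-3 s.
#'
#' @param geometry a packed `islet_geometry`.
#' @param plane_z plane position (um).
#' @param duration_s movie duration in seconds (the study's stimulation
#'   window is 1200 s; shorter movies are used for testing).
#' @param event_rate events per um of in-plane contact interface per minute
#'   (a per-area rate across a nominal 1 um optical section).
#' @param near_fraction probability that an event lies within 1 um of a
#'   capillary.
#' @param flash_params list: `amplitude`, `fwhm_um`, `tau_range` (s; decay
#'   constants drawn uniformly, 95%-return = 3*tau in 1-3 s by default).
#' @param noise_params list with `gaussian_sd`, `poisson_scale`.
#' @param background list with `dye` (extracellular intensity) and `cell`
#'   (intracellular floor).
#' @param frame_rate frames per second (default 6).
#' @param seed integer seed.
#' @param render_frames when `FALSE`, skip rendering the pixel data and
#'   return only the ground truth (fast path for statistical calibration
#'   over many replicates).
#' @return list with `movie` (a `fusion_movie`: frames array nx x ny x nT,
#'   `pixel_size`, `frame_rate`) and `ground_truth` (events data frame with
#'   `x_um`, `y_um`, `t_s`, `peak_frame`, `amplitude`, `tau_s`, `cell_id`,
#'   `near`; plus the per-cell contact-length table).
#' @export
simulate_fusion_movie <- function(geometry, plane_z, duration_s = 120,
                                  event_rate = 0.1, near_fraction = 0.8,
                                  flash_params = list(amplitude = 40,
                                                      fwhm_um = 1.0,
                                                      tau_range = c(0.34, 0.90)),
                                  noise_params = list(gaussian_sd = 3,
                                                      poisson_scale = 0),
                                  background = list(dye = 50, cell = 5),
                                  frame_rate = 6, seed = 1L,
                                  render_frames = TRUE) {
  stopifnot(inherits(geometry, "islet_geometry"))
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  if (event_rate < 0) stop("event_rate must be >= 0", call. = FALSE)
  stopifnot(near_fraction >= 0, near_fraction <= 1)
  sl <- plane_slice(geometry, plane_z)
  px <- sl$pixel_size
  d2 <- dim(sl$labels)
  n_frames <- max(2L, ceiling(duration_s * frame_rate))

  # stationary dye background (extracellular spaces are dye-filled)
  bg <- matrix(background$cell, d2[1], d2[2])
  bg[sl$labels == LBL_BG | sl$labels == LBL_CAP] <- background$dye
  bg3 <- array(bg, dim = c(d2, 1L))
  bg <- array(cpp_gauss_blur3d(as.numeric(bg3), dim(bg3),
                               c(0.15 / px, 0.15 / px, 0)), dim = d2)

  len <- inplane_contact_length(geometry, plane_z)
  res <- with_seed(seed, {
    events <- draw_events(sl, len, duration_s, event_rate, near_fraction,
                          flash_params, frame_rate, px)
    frames <- NULL
    if (render_frames) {
      frames <- array(rep(bg, n_frames), dim = c(d2, n_frames))
      frames <- add_flashes(frames, events, flash_params, frame_rate, px)
      gs <- noise_params$gaussian_sd %||% 0
      ps <- noise_params$poisson_scale %||% 0
      if (ps > 0) {
        frames[] <- rpois(length(frames), pmax(frames, 0) * ps) / ps
      }
      if (gs > 0) frames[] <- frames + rnorm(length(frames), 0, gs)
    }
    list(events = events, frames = frames)
  })

  movie <- if (render_frames) {
    structure(list(frames = res$frames, pixel_size = px,
                   frame_rate = frame_rate, plane_z = plane_z),
              class = "fusion_movie")
  }
  list(movie = movie,
       ground_truth = list(events = res$events, contact_length = len,
                           frame_rate = frame_rate, pixel_size = px,
                           plane_z = plane_z, duration_s = duration_s))
}

draw_events <- function(sl, len, duration_s, event_rate, near_fraction,
                        flash_params, frame_rate, px) {
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      t_s = numeric(0), peak_frame = integer(0),
                      amplitude = numeric(0), tau_s = numeric(0),
                      cell_id = integer(0), near = logical(0))
  if (event_rate == 0 || nrow(len) == 0L) return(empty)
  tau_range <- flash_params$tau_range %||% c(0.34, 0.90)
  amp <- flash_params$amplitude %||% 40
  rows <- list()
  for (i in seq_len(nrow(len))) {
    cid <- len$cell_id[i]
    lambda <- event_rate * len$contact_length_um[i] * duration_s / 60
    n_ev <- rpois(1, lambda)
    if (n_ev == 0) next
    cellmask <- sl$labels == cid
    near_pool <- which(sl$membrane & cellmask & sl$capdist < 1.0)
    far_pool <- which(sl$membrane & cellmask & sl$capdist >= 1.0)
    for (e in seq_len(n_ev)) {
      is_near <- runif(1) < near_fraction
      pool <- if (is_near) near_pool else far_pool
      if (length(pool) == 0L) {
        pool <- c(near_pool, far_pool)
        is_near <- length(far_pool) == 0L
      }
      p <- pool[sample.int(length(pool), 1L)]
      ij <- index_to_ijk(p, c(dim(sl$labels), 1L))[1, 1:2]
      t0 <- runif(1, 0, duration_s - 3)   # leave room for the decay
      pf <- floor(t0 * frame_rate) + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        x_um = (ij[1] - 0.5 + runif(1, -0.4, 0.4)) * px,
        y_um = (ij[2] - 0.5 + runif(1, -0.4, 0.4)) * px,
        t_s = (pf - 1) / frame_rate, peak_frame = pf,
        amplitude = amp * runif(1, 0.85, 1.15),
        tau_s = runif(1, tau_range[1], tau_range[2]),
        cell_id = cid, near = is_near
      )
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$t_s), , drop = FALSE]
}

# add Gaussian flashes with one-frame rise and exponential decay
add_flashes <- function(frames, events, flash_params, frame_rate, px) {
  if (nrow(events) == 0L) return(frames)
  fwhm <- flash_params$fwhm_um %||% 1.0
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r_px <- ceiling(3 * sigma / px)
  d <- dim(frames)
  for (e in seq_len(nrow(events))) {
    cx <- events$x_um[e] / px + 0.5   # pixel-centre coordinates
    cy <- events$y_um[e] / px + 0.5
    i0 <- max(1L, floor(cx - r_px))
    i1 <- min(d[1], ceiling(cx + r_px))
    j0 <- max(1L, floor(cy - r_px))
    j1 <- min(d[2], ceiling(cy + r_px))
    if (i0 > i1 || j0 > j1) next
    dx2 <- ((i0:i1 - 0.5) * px - events$x_um[e])^2
    dy2 <- ((j0:j1 - 0.5) * px - events$y_um[e])^2
    spot <- events$amplitude[e] *
      exp(-outer(dx2, dy2, "+") / (2 * sigma^2))
    tau_frames <- events$tau_s[e] * frame_rate
    f0 <- events$peak_frame[e]
    f1 <- min(d[3], f0 + ceiling(6 * tau_frames))
    if (f0 > d[3]) next
    decay <- exp(-(seq(f0, f1) - f0) / tau_frames)
    for (fi in seq_along(decay)) {
      frames[i0:i1, j0:j1, f0 + fi - 1L] <-
        frames[i0:i1, j0:j1, f0 + fi - 1L] + spot * decay[fi]
    }
  }
  frames
}

#' @export
print.fusion_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "Fusion movie: %d x %d px (%.2f um/px), %d frames at %g fps (%.1f s)\n",
    d[1], d[2], x$pixel_size, d[3], x$frame_rate, d[3] / x$frame_rate))
  invisible(x)
}
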