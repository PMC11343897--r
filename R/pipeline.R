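# End-to-end runner: simulate -> segment -> morphometry -> polarity ->
# detect -> statistics, governed by one config list (YAML-serialisable),
# with every artefact written to an output directory alongside a manifest
# carrying the resolved seed and a config hash.

#' Default pipeline configuration
#'
#' Every parameter with a printed value in the source protocol keeps it:
#' 6 frames/s, 0.7 um confirmation ROI, 5-pixel linescans, 60 s bins, 1 um
#' near threshold, 0.255 um voxels (0.336 um z available for the human
#' setting). Remaining values are the generator's study conditions.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    geometry = list(
      volume_um = c(40, 40, 40),
      voxel_size = c(0.255, 0.255, 0.255),
      n_tubes = 8L, radius_range = c(1.5, 2.5), tortuosity = 0.25,
      target_cell_diameter = 10, capsule_um = 1.0
    ),
    render = list(
      psf_sigma_um = c(0.15, 0.15, 0.45),
      noise = list(gaussian_sd = 2, poisson_scale = 0.5)
    ),
    segmentation = list(smoothing_sigma = 0.4, tunnel_radius_max = 4.0,
                        boundary_offset = 0.55, min_volume_um3 = 20),
    morphometry = list(contact_distance = 1.0, min_patch_area = 1.0),
    polarity = list(linescan_width_px = 5L),
    movie = list(
      duration_s = 120, frame_rate = 6, event_rate = 0.1,
      near_fraction = 0.8,
      flash = list(amplitude = 40, fwhm_um = 1.0,
                   tau_range = c(0.34, 0.90)),
      noise = list(gaussian_sd = 3, poisson_scale = 0)
    ),
    detection = list(z_threshold = 5, roi_diameter_um = 0.7),
    stats = list(near_threshold = 1.0, bin_width_s = 60),
    dbdb = list(enabled = FALSE, dilation_factor = 2)
  )
}

# deep-merge user config over defaults
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [default_config()].
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

# sub-seeds derived from the master seed (kept below 2^31)
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% .Machine$integer.max)
}

#' Run the full analysis pipeline on a synthetic islet
#'
#' Executes simulation, capillary segmentation, morphometry, polarity
#' profiling, fusion-event detection and event statistics, writing CSV/JSON
#' artefacts and TIFF volumes plus a manifest (resolved seed, parameter
#' echo, config hash) to `out_dir`. With `config$dbdb$enabled` the
#' morphometry block is additionally computed on the volume-preserving
#' capillary dilation.
#'
#' @param config configuration list (see [default_config()]).
#' @param out_dir output directory, created if needed.
#' @param write_volumes write TIFF stacks (label volume, laminin channel)?
#'   Disable for speed.
#' @param verbose print stage progress?
#' @return (invisibly) a list with all in-memory results: `geometry`,
#'   `morphometry` (measured), `morphometry_truth`, `polarity`, `events`,
#'   `event_stats`, `manifest`, and `dbdb` when enabled.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         write_volumes = TRUE, verbose = TRUE) {
  t_all <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("[%s] done in %.1f s", name, as.numeric(Sys.time() - t0, "secs"))
    r
  }
  cfg <- config
  vs <- cfg$geometry$voxel_size

  geometry <- stage("simulate", {
    g <- generate_capillary_network(
      round(cfg$geometry$volume_um / vs), voxel_size = vs,
      n_tubes = cfg$geometry$n_tubes,
      radius_range = cfg$geometry$radius_range,
      tortuosity = cfg$geometry$tortuosity,
      seed = stage_seed(cfg$seed, 1)
    )
    pack_cells(g, target_cell_diameter = cfg$geometry$target_cell_diameter,
               capsule_um = cfg$geometry$capsule_um,
               contact_distance = cfg$morphometry$contact_distance,
               min_patch_area = cfg$morphometry$min_patch_area,
               seed = stage_seed(cfg$seed, 2))
  })
  channels <- stage("render", {
    render_channels(geometry, psf_sigma_um = cfg$render$psf_sigma_um,
                    noise_params = cfg$render$noise,
                    seed = stage_seed(cfg$seed, 3))
  })
  cap_seg <- stage("segment", {
    segment_capillaries(channels$laminin, geometry$islet_mask, vs,
                        smoothing_sigma = cfg$segmentation$smoothing_sigma,
                        tunnel_radius_max = cfg$segmentation$tunnel_radius_max,
                        boundary_offset = cfg$segmentation$boundary_offset,
                        min_volume_um3 = cfg$segmentation$min_volume_um3)
  })
  morpho <- stage("morphometry", {
    morphometry_report(geometry$labels, cap_seg, geometry$islet_mask, vs,
                       contact_distance = cfg$morphometry$contact_distance,
                       min_patch_area = cfg$morphometry$min_patch_area)
  })
  morpho_truth <- stage("morphometry-truth", {
    morphometry_report(geometry$labels, geometry$labels == LBL_CAP,
                       geometry$islet_mask, vs,
                       contact_distance = cfg$morphometry$contact_distance,
                       min_patch_area = cfg$morphometry$min_patch_area)
  })
  polarity <- stage("polarity", {
    prof <- cell_polarity_profiles(
      geometry, channels, width_px = cfg$polarity$linescan_width_px)
    tests <- lapply(split(prof, prof$channel), function(ch) {
      tryCatch(enrichment_test(ch), error = function(e) NULL)
    })
    list(profiles = prof, tests = tests)
  })
  plane_z <- cfg$geometry$volume_um[3] / 2
  sim <- stage("movie", {
    simulate_fusion_movie(
      geometry, plane_z, duration_s = cfg$movie$duration_s,
      event_rate = cfg$movie$event_rate,
      near_fraction = cfg$movie$near_fraction,
      flash_params = cfg$movie$flash, noise_params = cfg$movie$noise,
      frame_rate = cfg$movie$frame_rate, seed = stage_seed(cfg$seed, 4)
    )
  })
  events <- stage("detect", {
    detect_events(sim$movie, z_threshold = cfg$detection$z_threshold,
                  roi_diameter_um = cfg$detection$roi_diameter_um)
  })
  ev_stats <- stage("stats", {
    pipeline_event_stats(geometry, sim, events, cfg, plane_z)
  })
  dbdb <- NULL
  if (isTRUE(cfg$dbdb$enabled)) {
    dbdb <- stage("dbdb", {
      gp <- perturb_dbdb(geometry, cfg$dbdb$dilation_factor)
      morphometry_report(gp$labels, gp$labels == LBL_CAP, gp$islet_mask,
                         vs,
                         contact_distance = cfg$morphometry$contact_distance,
                         min_patch_area = cfg$morphometry$min_patch_area)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("isletcap")),
    resolved_seed = cfg$seed,
    config = cfg,
    config_hash = config_hash(cfg),
    n_cells = length(geometry$cell_ids),
    n_events_detected = nrow(events),
    runtime_s = as.numeric(Sys.time() - t_all, "secs")
  )
  stage("write", {
    write_outputs(out_dir, cfg, geometry, channels, morpho, morpho_truth,
                  polarity, events, ev_stats, dbdb, manifest,
                  write_volumes)
  })
  invisible(list(geometry = geometry, morphometry = morpho,
                 morphometry_truth = morpho_truth, polarity = polarity,
                 movie = sim, events = events, event_stats = ev_stats,
                 dbdb = dbdb, manifest = manifest))
}

# event statistics block of the pipeline
pipeline_event_stats <- function(geometry, sim, events, cfg, plane_z) {
  sl <- plane_slice(geometry, plane_z)
  nt <- cfg$stats$near_threshold
  len <- sim$ground_truth$contact_length
  if (nrow(events) > 0) {
    events <- distance_to_capillary(events, sl$labels == LBL_CAP,
                                    sl$pixel_size, nt)
    # attribute each detection to the nearest cell in the plane
    i <- pmin(pmax(round(events$x_um / sl$pixel_size + 0.5), 1L),
              nrow(sl$labels))
    j <- pmin(pmax(round(events$y_um / sl$pixel_size + 0.5), 1L),
              ncol(sl$labels))
    lab_at <- sl$labels[cbind(i, j)]
    events$cell_id <- ifelse(lab_at >= CELL_ID_START, lab_at, NA_integer_)
    miss <- which(is.na(events$cell_id))
    for (m in miss) {   # events on membrane pixels rounded into gaps
      win <- expand.grid(di = -2:2, dj = -2:2)
      li <- pmin(pmax(i[m] + win$di, 1L), nrow(sl$labels))
      lj <- pmin(pmax(j[m] + win$dj, 1L), ncol(sl$labels))
      cand <- sl$labels[cbind(li, lj)]
      cand <- cand[cand >= CELL_ID_START]
      if (length(cand) > 0) events$cell_id[m] <- cand[1]
    }
  } else {
    events$capillary_distance_um <- numeric(0)
    events$near <- logical(0)
    events$cell_id <- integer(0)
  }
  rates <- suppressWarnings(events_per_capillary_length(events, len))
  nf <- if (nrow(rates) >= 2) {
    near_far_test(rates$near_rate, rates$far_rate)
  } else {
    list(p_value = NA_real_, n_pairs = 0L, statistic = NA_real_)
  }
  per_cell <- attr(geometry$contacts, "cell_surface")
  area <- tapply(geometry$contacts$area_um2, geometry$contacts$cell_id, sum)
  counts <- table(factor(events$cell_id,
                         levels = names(area)))
  reg <- if (length(area) >= 3 && sd(area) > 1e-12) {
    events_vs_area_regression(as.numeric(counts), as.numeric(area))
  } else {
    NULL
  }
  list(events = events, rates = rates, near_far = nf, regression = reg)
}

config_hash <- function(cfg) {
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(js, f)
  unname(tools::md5sum(f))
}

write_outputs <- function(out_dir, cfg, geometry, channels, morpho,
                          morpho_truth, polarity, events, ev_stats, dbdb,
                          manifest, write_volumes) {
  p <- function(...) file.path(out_dir, ...)
  yaml::write_yaml(cfg, p("config.yaml"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  add_hash <- function(df) {
    if (nrow(df) > 0) df$config_hash <- manifest$config_hash
    df
  }
  write.csv(add_hash(morpho$per_cell), p("per_cell_morphometry.csv"),
            row.names = FALSE)
  write.csv(add_hash(morpho$patches), p("contact_patches.csv"),
            row.names = FALSE)
  write.csv(add_hash(polarity$profiles), p("polarity_profiles.csv"),
            row.names = FALSE)
  write.csv(add_hash(events), p("events.csv"), row.names = FALSE)
  write.csv(add_hash(ev_stats$rates), p("near_far_rates.csv"),
            row.names = FALSE)
  summary <- list(
    config_hash = manifest$config_hash,
    capillary_volume_fraction = morpho$capillary_volume_fraction,
    capillary_surface_area_density = morpho$capillary_surface_area_density,
    contact_proportions = as.list(morpho$contact_proportions),
    truth_contact_proportions = as.list(morpho_truth$contact_proportions),
    n_events = nrow(events),
    near_far_p = ev_stats$near_far$p_value,
    regression = if (!is.null(ev_stats$regression)) {
      ev_stats$regression[c("slope", "intercept", "r_squared", "p_value",
                            "n_cells")]
    }
  )
  if (!is.null(dbdb)) {
    summary$dbdb <- list(
      capillary_volume_fraction = dbdb$capillary_volume_fraction,
      capillary_surface_area_density = dbdb$capillary_surface_area_density,
      contact_proportions = as.list(dbdb$contact_proportions)
    )
  }
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (write_volumes) {
    write_stack(geometry$labels, p("labels.tif"), geometry$voxel_size,
                type = "label")
    write_stack(channels$laminin, p("laminin.tif"), geometry$voxel_size,
                type = "intensity")
  }
  invisible(out_dir)
}
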