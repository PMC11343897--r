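# Synthetic islet geometry: a tortuous capillary network threaded through a
# packed bed of ~10 um endocrine cells, with ground-truth contact patches.
# The generator exists to give every analysis stage a known answer; it is the
# package's source of validation data because the imaging volumes the method
# is designed for are not something a test suite can carry.

#' Generate a tortuous capillary network
#'
#' Builds the capillary scaffold of a synthetic islet: `n_tubes` tubes of
#' random radius around smoothed 3D random-walk centerlines that traverse the
#' volume, rasterised onto an anisotropic voxel grid. Cells are added with
#' [pack_cells()].
#'
#' @param volume_shape integer voxel dimensions `c(nx, ny, nz)`.
#' @param voxel_size voxel spacing `c(dx, dy, dz)` in micrometres. Defaults to
#'   the mouse confocal setting (0.255 um isotropic); use `dz = 0.336` for the
#'   human z-step.
#' @param n_tubes number of capillary tubes (>= 0).
#' @param radius_range tube radius range in micrometres; each tube draws its
#'   radius uniformly from this interval.
#' @param tortuosity angular SD (radians) of the per-step direction change of
#'   the centerline random walk; 0 gives straight tubes.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @return an `islet_geometry` object: integer label array (`0` background,
#'   `1` capillary lumen), `voxel_size`, centerline polylines (um), and the
#'   tube list needed by [perturb_dbdb()].
#' @export
generate_capillary_network <- function(volume_shape,
                                       voxel_size = c(0.255, 0.255, 0.255),
                                       n_tubes = 8L,
                                       radius_range = c(1.5, 2.5),
                                       tortuosity = 0.25,
                                       seed = 1L) {
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 1),
            n_tubes >= 0, all(radius_range > 0), !missing(seed))
  volume_um <- volume_shape * voxel_size
  if (n_tubes > 0 && min(volume_um) < 2 * min(radius_range)) {
    stop("volume too small to fit one tube of minimum radius ",
         min(radius_range), " um", call. = FALSE)
  }
  tubes <- with_seed(seed, {
    lapply(seq_len(n_tubes), function(i) {
      r <- runif(1, radius_range[1], radius_range[2])
      list(centerline = random_walk_centerline(volume_um, r, tortuosity),
           radius = r)
    })
  })
  labels <- array(LBL_BG, dim = volume_shape)
  if (n_tubes > 0) {
    cap <- rasterise_tubes(tubes, volume_shape, voxel_size)
    labels[cap] <- LBL_CAP
  }
  structure(
    list(
      labels = labels,
      voxel_size = voxel_size,
      volume_um = volume_um,
      tubes = tubes,
      centerlines = lapply(tubes, `[[`, "centerline"),
      islet_mask = array(TRUE, dim = volume_shape),
      cell_ids = integer(0),
      contacts = NULL,
      params = list(network = list(volume_shape = volume_shape,
                                   voxel_size = voxel_size,
                                   n_tubes = n_tubes,
                                   radius_range = radius_range,
                                   tortuosity = tortuosity,
                                   seed = seed))
    ),
    class = "islet_geometry"
  )
}

# bounded-curvature random walk spanning the volume along a random axis
random_walk_centerline <- function(volume_um, radius, tortuosity,
                                   step = 0.5) {
  axis <- sample(3L, 1L)
  margin <- pmin(radius, volume_um / 4)
  pos <- runif(3, margin, volume_um - margin)
  pos[axis] <- 0
  dir <- rnorm(3, 0, 0.1)
  dir[axis] <- 1
  dir <- dir / sqrt(sum(dir^2))
  pts <- matrix(pos, nrow = 1L)
  max_steps <- ceiling(4 * sum(volume_um) / step)
  for (s in seq_len(max_steps)) {
    if (tortuosity > 0) {
      dir <- dir + rnorm(3, 0, tortuosity)
      dir <- dir / sqrt(sum(dir^2))
    }
    if (dir[axis] < 0.15) dir[axis] <- 0.15   # keep traversing
    dir <- dir / sqrt(sum(dir^2))
    pos <- pos + step * dir
    for (a in setdiff(1:3, axis)) {           # reflect at lateral walls
      if (pos[a] < margin[a]) {
        pos[a] <- 2 * margin[a] - pos[a]
        dir[a] <- -dir[a]
      } else if (pos[a] > volume_um[a] - margin[a]) {
        pos[a] <- 2 * (volume_um[a] - margin[a]) - pos[a]
        dir[a] <- -dir[a]
      }
    }
    pts <- rbind(pts, pos)
    if (pos[axis] >= volume_um[axis]) break
  }
  unname(pts)
}

# union of tubes: mark centerline samples, EDT, threshold at each radius
rasterise_tubes <- function(tubes, d, voxel_size) {
  mask <- array(FALSE, dim = d)
  for (tube in tubes) {
    mask <- mask | rasterise_one_tube(tube, d, voxel_size)
  }
  mask
}

rasterise_one_tube <- function(tube, d, voxel_size) {
  pts <- resample_polyline(tube$centerline, min(voxel_size) / 2)
  array(cpp_paint_balls(pts, tube$radius, d, voxel_size), dim = d)
}

# resample a polyline to roughly uniform spacing
resample_polyline <- function(pts, spacing) {
  if (nrow(pts) < 2L) return(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) return(pts[1, , drop = FALSE])
  s <- seq(0, total, by = spacing)
  out <- sapply(1:3, function(a) approx(cum, pts[, a], xout = s)$y)
  matrix(out, ncol = 3L)
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Pack cells into a capillary network
#'
#' Tessellates the non-capillary islet interior into contiguous cell regions
#' by seeded geodesic region growing (a Voronoi-like partition that respects
#' the capillary lumen), adds a peripheral capsule shell, carves thin
#' interstitial canaliculi along junctions where three or more cells meet
#' away from capillaries (the luminal spaces that define the apical domain),
#' and records ground-truth capillary contact patches per cell from the true
#' labels.
#'
#' @param geometry an `islet_geometry` from [generate_capillary_network()].
#' @param target_cell_diameter mean cell diameter in micrometres (default 10,
#'   the textbook beta-cell size).
#' @param capsule_um thickness of the capsule shell at the volume boundary.
#' @param interstitial_radius radius (um) of the carved luminal canaliculi.
#' @param contact_distance,min_patch_area ground-truth contact definition,
#'   passed to [cell_contact_patches()].
#' @param seed integer seed for seed-point placement.
#' @return the geometry with cell labels (ids from 10), `cell_ids`,
#'   `islet_mask` and `contacts` (ground-truth patch table) filled in.
#' @export
pack_cells <- function(geometry, target_cell_diameter = 10,
                       capsule_um = 1.0, interstitial_radius = 0.4,
                       contact_distance = 1.0, min_patch_area = 1.0,
                       seed = 1L) {
  stopifnot(inherits(geometry, "islet_geometry"))
  d <- dim(geometry$labels)
  vs <- geometry$voxel_size
  if (target_cell_diameter >= min(geometry$volume_um)) {
    stop("target cell diameter larger than the domain", call. = FALSE)
  }
  labels <- geometry$labels
  labels[labels >= CELL_ID_START] <- LBL_BG   # idempotent re-pack

  # capsule: shell of extracellular matrix at the volume boundary
  ax <- function(n, dd) pmin((seq_len(n) - 0.5) * dd,
                             (n - seq_len(n) + 0.5) * dd)
  edge <- outer(outer(ax(d[1], vs[1]), ax(d[2], vs[2]), pmin),
                ax(d[3], vs[3]), pmin)
  capsule <- edge < capsule_um & labels == LBL_BG
  labels[capsule] <- LBL_CAPSULE
  islet_mask <- array(edge >= capsule_um, dim = d)

  available <- labels == LBL_BG
  vox_vol <- prod(vs)
  cell_vol <- pi / 6 * target_cell_diameter^3
  n_cells <- max(1L, round(sum(available) * vox_vol / cell_vol))

  seeds_idx <- with_seed(seed, {
    cand <- sample(which(available), min(50L * n_cells, sum(available)))
    pick_separated(cand, d, vs, min_sep = 0.7 * target_cell_diameter,
                   n_max = n_cells)
  })
  seed_arr <- array(0L, dim = d)
  seed_arr[seeds_idx] <- CELL_ID_START + seq_along(seeds_idx) - 1L

  grown <- cpp_region_grow(seed_arr, available, d, vs)
  labels[available] <- grown[available]

  # carve luminal canaliculi along >=3-cell junction edges away from vessels
  capdist <- if (any(labels == LBL_CAP)) {
    distance_map(labels == LBL_CAP, vs)
  } else {
    array(Inf, dim = d)
  }
  junction <- array(cpp_junction_mask(labels, d, 3L, CELL_ID_START), dim = d)
  junction <- junction & capdist > 2.0
  if (any(junction)) {
    jd <- distance_map(junction, vs)
    carve <- jd <= interstitial_radius & labels >= CELL_ID_START &
      capdist > 2.0
    labels[carve] <- LBL_BG
  }

  # enforce one connected component per cell: strays become interstitial
  comp <- label_same_components(ifelse(labels >= CELL_ID_START, labels, 0L))
  if (max(comp) > 0) {
    sizes <- tabulate(comp)
    comp_label <- labels[match(seq_len(max(comp)), comp)]
    keep <- unlist(lapply(split(seq_len(max(comp)), comp_label), function(ix) {
      ix[which.max(sizes[ix])]
    }), use.names = FALSE)
    stray <- comp > 0 & !(comp %in% keep)
    labels[stray] <- LBL_BG
  }

  cell_ids <- sort(unique(labels[labels >= CELL_ID_START]))
  geometry$labels <- labels
  geometry$islet_mask <- islet_mask
  geometry$cell_ids <- cell_ids
  geometry$contacts <- cell_contact_patches(
    labels, labels == LBL_CAP, vs,
    contact_distance = contact_distance, min_patch_area = min_patch_area
  )
  geometry$params$packing <- list(
    target_cell_diameter = target_cell_diameter, capsule_um = capsule_um,
    interstitial_radius = interstitial_radius,
    contact_distance = contact_distance, min_patch_area = min_patch_area,
    seed = seed
  )
  geometry
}

# greedy Poisson-disk-style thinning of candidate voxel indices
pick_separated <- function(cand, d, vs, min_sep, n_max) {
  xyz <- voxel_centers(index_to_ijk(cand, d), vs)
  acc <- integer(0)
  acc_xyz <- matrix(numeric(0), ncol = 3L)
  for (i in seq_along(cand)) {
    if (length(acc) >= n_max) break
    p <- xyz[i, ]
    if (nrow(acc_xyz) == 0L ||
        min(sqrt(colSums((t(acc_xyz) - p)^2))) >= min_sep) {
      acc <- c(acc, cand[i])
      acc_xyz <- rbind(acc_xyz, p)
    }
  }
  acc
}

#' Emulate the diabetic (db/db) capillary remodelling
#'
#' Widens capillary tubes by `dilation_factor` while pruning the tube count
#' so that total capillary volume is preserved (within 5%), reproducing the
#' observed remodelling pattern: unchanged capillary volume fraction with
#' reduced surface area and reduced per-cell contact. Cells are re-packed
#' with the original packing parameters and ground-truth contacts are
#' recomputed.
#'
#' @param geometry a packed `islet_geometry` (or capillaries-only geometry).
#' @param dilation_factor radial dilation (>= 1); 1 returns the geometry
#'   unchanged.
#' @return a new `islet_geometry`.
#' @export
perturb_dbdb <- function(geometry, dilation_factor) {
  stopifnot(inherits(geometry, "islet_geometry"), dilation_factor >= 1)
  if (dilation_factor == 1) return(geometry)
  tubes <- geometry$tubes
  n <- length(tubes)
  if (n == 0L) stop("geometry has no capillary tubes", call. = FALSE)
  d <- dim(geometry$labels)
  vs <- geometry$voxel_size
  # preserve capillary volume inside the islet proper: tube stubs in the
  # capsule margin scale differently under dilation and are not analysed
  inside <- geometry$islet_mask
  v0 <- sum(geometry$labels == LBL_CAP & inside)

  dil <- lapply(tubes, function(t) {
    t$radius <- t$radius * dilation_factor
    t
  })
  # cumulative union volume as dilated tubes are added
  acc <- array(FALSE, dim = d)
  vols <- numeric(n)
  for (k in seq_len(n)) {
    acc <- acc | rasterise_one_tube(dil[[k]], d, vs)
    vols[k] <- sum(acc & inside)
  }
  k <- which.min(abs(vols - v0))
  # iterative radial correction towards exact volume preservation: volume
  # scales roughly as r^2 but tube overlaps bend the exponent, so refine
  corr <- 1
  dil_k <- dil[seq_len(k)]
  cap <- NULL
  ratio <- vols[k] / v0
  for (it in 1:5) {
    corr <- min(max(corr * sqrt(1 / ratio), 0.6), 1.6)
    trial <- lapply(dil_k, function(t) {
      t$radius <- t$radius * corr
      t
    })
    cap <- rasterise_tubes(trial, d, vs)
    ratio <- sum(cap & inside) / v0
    if (abs(ratio - 1) < 0.02) {
      dil_k <- trial
      break
    }
    if (it == 5) dil_k <- trial
  }
  if (abs(ratio - 1) > 0.05) {
    stop(sprintf(
      "cannot preserve capillary volume within 5%% (achieved ratio %.3f)",
      ratio), call. = FALSE)
  }

  out <- geometry
  out$labels <- array(LBL_BG, dim = d)
  out$labels[cap] <- LBL_CAP
  out$tubes <- dil_k
  out$centerlines <- lapply(dil_k, `[[`, "centerline")
  out$cell_ids <- integer(0)
  out$contacts <- NULL
  out$params$dbdb <- list(dilation_factor = dilation_factor,
                          kept_tubes = k, volume_ratio = ratio)
  if (length(geometry$cell_ids) > 0) {
    p <- geometry$params$packing
    out <- pack_cells(out, target_cell_diameter = p$target_cell_diameter,
                      capsule_um = p$capsule_um,
                      interstitial_radius = p$interstitial_radius,
                      contact_distance = p$contact_distance,
                      min_patch_area = p$min_patch_area, seed = p$seed)
    out$params$dbdb <- list(dilation_factor = dilation_factor,
                            kept_tubes = k, volume_ratio = ratio)
  }
  out
}

#' @export
print.islet_geometry <- function(x, ...) {
  d <- dim(x$labels)
  cat("Synthetic islet geometry\n")
  cat(sprintf("  volume: %d x %d x %d voxels (%.1f x %.1f x %.1f um)\n",
              d[1], d[2], d[3], x$volume_um[1], x$volume_um[2],
              x$volume_um[3]))
  cat(sprintf("  voxel size: %.3f x %.3f x %.3f um\n", x$voxel_size[1],
              x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  capillary tubes: %d (%.1f%% of volume)\n", length(x$tubes),
              100 * mean(x$labels == LBL_CAP)))
  cat(sprintf("  cells: %d\n", length(x$cell_ids)))
  if (!is.null(x$contacts)) {
    cat(sprintf("  ground-truth contact patches: %d\n", nrow(x$contacts)))
  }
  invisible(x)
}
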