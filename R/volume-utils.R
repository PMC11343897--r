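# Shared grid conventions and thin wrappers around the compiled primitives.
#
# Volumes are base-R 3D arrays, dim = c(nx, ny, nz), x varying fastest.
# Voxel i (1-based) spans [(i-1)*d, i*d] um along its axis; its centre is at
# (i - 0.5)*d. All physical quantities are micrometres.

# label scheme used by the synthetic generator
LBL_BG <- 0L       # exterior / interstitial (extracellular, dye-accessible)
LBL_CAP <- 1L      # capillary lumen
LBL_CAPSULE <- 2L  # islet capsule (peripheral ECM sheath)
CELL_ID_START <- 10L

#' Evaluate an expression with a private RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so generator functions are deterministic without
#' disturbing the session RNG.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

check_volume <- function(vol, name = "volume") {
  if (!is.array(vol) || length(dim(vol)) != 3L) {
    stop(sprintf("`%s` must be a 3D array", name), call. = FALSE)
  }
  invisible(vol)
}

#' Anisotropic Gaussian blur of a 3D volume
#' @param vol 3D numeric array.
#' @param sigma_um Gaussian SD per axis in micrometres (length 1 or 3).
#' @param voxel_size voxel spacing (dx, dy, dz) in micrometres.
#' @return blurred array, same dimensions.
#' @export
gauss_blur <- function(vol, sigma_um, voxel_size) {
  check_volume(vol)
  sigma_um <- rep(sigma_um, length.out = 3L)
  sv <- sigma_um / voxel_size
  out <- cpp_gauss_blur3d(as.numeric(vol), dim(vol), sv)
  array(out, dim(vol))
}

#' Euclidean distance transform on the physical grid
#'
#' Distance in micrometres from every voxel centre to the nearest `TRUE`
#' voxel centre, honouring anisotropic spacing.
#' @param mask 3D logical array.
#' @param voxel_size voxel spacing in micrometres.
#' @return numeric array of distances; `Inf`-like large values if `mask` is
#'   empty.
#' @export
distance_map <- function(mask, voxel_size) {
  check_volume(mask)
  out <- cpp_edt3d(as.logical(mask), dim(mask), voxel_size)
  array(out, dim(mask))
}

#' Label connected components of a 3D mask
#' @param mask 3D logical array.
#' @param connectivity 6 or 26.
#' @return integer array; 0 outside, components numbered from 1 in scan
#'   order.
#' @export
label_components <- function(mask, connectivity = 6L) {
  check_volume(mask)
  stopifnot(connectivity %in% c(6L, 26L))
  array(cpp_label3d(as.logical(mask), dim(mask), as.integer(connectivity)),
        dim(mask))
}

# components that never merge across different input labels
label_same_components <- function(lab, connectivity = 6L) {
  array(cpp_label_same3d(as.integer(lab), dim(lab),
                         as.integer(connectivity)), dim(lab))
}

# voxels whose 6-neighbourhood contains a different label
boundary_mask <- function(lab) {
  array(cpp_boundary_mask(as.integer(lab), dim(lab)), dim(lab))
}

# fill cavities: complement components not connected to the volume border
fill_holes <- function(mask) {
  fill_holes_bounded(mask, max_fraction = 1)
}

# fill enclosed cavities no larger than max_fraction of the volume -- a
# vessel lumen is a small enclosed space, whereas the interior enclosed by a
# stained capsule shell is most of the volume and must not be filled
fill_holes_bounded <- function(mask, max_fraction = 0.25) {
  comp <- label_components(!mask, connectivity = 6L)
  d <- dim(mask)
  border <- c(
    if (d[1] > 1) c(comp[1, , ], comp[d[1], , ]),
    if (d[2] > 1) c(comp[, 1, ], comp[, d[2], ]),
    if (d[3] > 1) c(comp[, , 1], comp[, , d[3]])
  )
  border <- unique(border[border > 0])
  if (max(comp) == 0) return(mask)
  sizes <- tabulate(comp[comp > 0], nbins = max(comp))
  fillable <- setdiff(which(sizes <= max_fraction * length(mask)), border)
  mask | (comp > 0 & comp %in% fillable)
}

# tube-aware filling: a lumen whose tube leaves the volume is not a 3D
# cavity (it opens at the faces), but its cross-section is enclosed in
# slices perpendicular to the local axis -- fill 2D holes slice-wise along
# all three axes and union with the 3D fill
fill_tube_lumens <- function(mask, max_fraction = 0.25) {
  out <- fill_holes_bounded(mask, max_fraction)
  d <- dim(mask)
  for (axis in 1:3) {
    n <- d[axis]
    for (k in seq_len(n)) {
      sl <- switch(axis, mask[k, , ], mask[, k, ], mask[, , k])
      d2 <- dim(sl)
      filled <- fill_holes_bounded(array(sl, dim = c(d2, 1L)),
                                   max_fraction)
      add <- array(filled, dim = d2) & !sl
      if (!any(add)) next
      switch(axis,
             {out[k, , ][add] <- TRUE},
             {out[, k, ][add] <- TRUE},
             {out[, , k][add] <- TRUE})
    }
  }
  out
}

# physical centre coordinates (um) of voxel indices (matrix of 1-based ijk)
voxel_centers <- function(ijk, voxel_size) {
  sweep(ijk - 0.5, 2L, voxel_size, "*")
}

# linear index -> (i, j, k) matrix
index_to_ijk <- function(idx, d) {
  idx0 <- idx - 1L
  cbind(
    i = idx0 %% d[1] + 1L,
    j = (idx0 %/% d[1]) %% d[2] + 1L,
    k = idx0 %/% (d[1] * d[2]) + 1L
  )
}
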