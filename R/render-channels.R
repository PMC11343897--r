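# Synthetic marker channels: domain-specific enrichment painted on the
# labelled geometry, blurred by an anisotropic Gaussian PSF and corrupted
# with Poisson-Gaussian noise -- the standard confocal approximation.

MARKER_CLASSES <- c("capillary_surface", "membrane_uniform",
                    "lateral_membrane", "apical_membrane", "contact_patch",
                    "cytoplasm")

#' Define a marker channel
#'
#' @param name channel name.
#' @param localisation one of `"capillary_surface"` (basement membrane around
#'   the lumen plus capsule, laminin-like), `"membrane_uniform"` (all cell
#'   membrane, Dlg-like), `"lateral_membrane"` (cell-cell interfaces,
#'   E-cadherin-like), `"apical_membrane"` (membrane on luminal spaces away
#'   from capillaries, Par3-like), `"contact_patch"` (membrane at capillary
#'   contacts, liprin/pFAK-like) or `"cytoplasm"` (insulin-like).
#' @param enrichment ratio of in-domain to out-of-domain mean intensity
#'   (>= 1).
#' @param baseline out-of-domain intensity.
#' @return a `marker_spec` list.
#' @export
marker_spec <- function(name, localisation, enrichment = 5, baseline = 10) {
  if (!localisation %in% MARKER_CLASSES) {
    stop("unknown localisation class: ", localisation, call. = FALSE)
  }
  stopifnot(enrichment >= 1, baseline > 0)
  structure(list(name = name, localisation = localisation,
                 enrichment = enrichment, baseline = baseline),
            class = "marker_spec")
}

#' The default six-channel marker panel
#'
#' Emulates the immunofluorescence panel of the study system: laminin
#' (vessels + capsule), insulin (cytoplasm), E-cadherin (lateral), Dlg
#' (uniform membrane), Par3 (apical) and a presynaptic scaffold marker such
#' as liprin (capillary contact patches).
#' @return named list of [marker_spec()] objects.
#' @export
default_marker_panel <- function() {
  list(
    laminin = marker_spec("laminin", "capillary_surface", 8),
    insulin = marker_spec("insulin", "cytoplasm", 4),
    ecad = marker_spec("ecad", "lateral_membrane", 4),
    dlg = marker_spec("dlg", "membrane_uniform", 4),
    par3 = marker_spec("par3", "apical_membrane", 6),
    liprin = marker_spec("liprin", "contact_patch", 8)
  )
}

# 6-neighbour adjacency flags for every cell-membrane voxel:
# does the voxel touch background (label 0) / another cell?
adjacency_flags <- function(labels) {
  d <- dim(labels)
  is_cell <- labels >= CELL_ID_START
  touch_bg <- array(FALSE, d)
  touch_cell <- array(FALSE, d)
  shift_pairs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                      c(0, 0, 1), c(0, 0, -1))
  for (s in shift_pairs) {
    nb <- shift_labels(labels, s)
    touch_bg <- touch_bg | (!is.na(nb) & nb == LBL_BG)
    touch_cell <- touch_cell |
      (!is.na(nb) & nb >= CELL_ID_START & nb != labels)
  }
  list(bg = touch_bg & is_cell, cell = touch_cell & is_cell)
}

# shift a 3D array by one voxel; NA outside the volume
shift_labels <- function(a, s) {
  d <- dim(a)
  out <- array(NA_integer_, d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (ax in 1:3) {
    if (s[ax] == 1) {
      dst[[ax]] <- 1:(d[ax] - 1)
      src[[ax]] <- 2:d[ax]
    } else if (s[ax] == -1) {
      dst[[ax]] <- 2:d[ax]
      src[[ax]] <- 1:(d[ax] - 1)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# localisation-class masks shared by all channels of one geometry. Membrane
# paints extend paint_thickness into the cell: junctional and scaffold
# protein zones have sub-micron but finite depth, and a one-voxel sheet
# would be washed out by the axial PSF.
domain_masks <- function(geometry, contact_distance = 1.0,
                         wall_thickness = 0.4, paint_thickness = 0.3) {
  labels <- geometry$labels
  vs <- geometry$voxel_size
  is_cell <- labels >= CELL_ID_START
  membrane <- boundary_mask(labels) & is_cell
  capdist <- if (any(labels == LBL_CAP)) {
    distance_map(labels == LBL_CAP, vs)
  } else {
    array(Inf, dim = dim(labels))
  }
  contact <- membrane & capdist <= contact_distance
  adj <- adjacency_flags(labels)
  apical <- membrane & !contact & adj$bg       # precedence: capillary > apical
  lateral <- membrane & !contact & !apical
  thicken <- function(dom) {
    if (paint_thickness <= 0 || !any(dom)) return(dom)
    # deepen the paint into the cell without crossing onto the membrane
    # path of a neighbouring domain
    (distance_map(dom, vs) <= paint_thickness & is_cell & !membrane) | dom
  }
  list(
    capillary_surface = (capdist > 0 & capdist <= wall_thickness &
                           labels != LBL_CAP) | labels == LBL_CAPSULE,
    membrane_uniform = thicken(membrane),
    lateral_membrane = thicken(lateral),
    apical_membrane = thicken(apical),
    contact_patch = thicken(contact),
    cytoplasm = is_cell
  )
}

#' Render fluorescence channels for a synthetic islet
#'
#' Each channel is `baseline` everywhere plus `baseline * (enrichment - 1)`
#' on its localisation class, blurred by an anisotropic Gaussian PSF and
#' corrupted by Poisson noise on the scaled intensity plus additive Gaussian
#' read noise.
#'
#' @param geometry a packed `islet_geometry`.
#' @param marker_specs list of [marker_spec()] objects.
#' @param psf_sigma_um PSF Gaussian SD `c(x, y, z)` in micrometres.
#' @param noise_params list with `gaussian_sd` (additive read noise) and
#'   `poisson_scale` (photons per intensity unit; 0 disables shot noise).
#' @param seed integer seed.
#' @param contact_distance passed to the contact-patch mask.
#' @return named list of 3D intensity arrays with attributes `voxel_size`
#'   and `specs`.
#' @export
render_channels <- function(geometry, marker_specs = default_marker_panel(),
                            psf_sigma_um = c(0.15, 0.15, 0.45),
                            noise_params = list(gaussian_sd = 2,
                                                poisson_scale = 0.5),
                            seed = 1L, contact_distance = 1.0) {
  stopifnot(inherits(geometry, "islet_geometry"))
  masks <- domain_masks(geometry, contact_distance)
  n_vox <- length(geometry$labels)
  out <- with_seed(seed, {
    lapply(marker_specs, function(sp) {
      if (!inherits(sp, "marker_spec")) {
        stop("marker_specs must be marker_spec objects", call. = FALSE)
      }
      img <- array(sp$baseline, dim = dim(geometry$labels))
      img[masks[[sp$localisation]]] <- sp$baseline * sp$enrichment
      img <- gauss_blur(img, psf_sigma_um, geometry$voxel_size)
      add_poisson_gaussian(img, noise_params)
    })
  })
  names(out) <- vapply(marker_specs, `[[`, "", "name")
  attr(out, "voxel_size") <- geometry$voxel_size
  attr(out, "specs") <- marker_specs
  out
}

# Poisson shot noise on scaled intensity + additive Gaussian read noise
add_poisson_gaussian <- function(img, noise_params) {
  gs <- noise_params$gaussian_sd %||% 0
  ps <- noise_params$poisson_scale %||% 0
  if (ps > 0) {
    img[] <- rpois(length(img), pmax(img, 0) * ps) / ps
  }
  if (gs > 0) {
    img[] <- img + rnorm(length(img), 0, gs)
  }
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a
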