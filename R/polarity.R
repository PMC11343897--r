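# 3D cell-polarity quantification: the membrane of a cell with capillary
# contacts is partitioned into capillary (basal), lateral and apical
# domains; marker intensity is measured by width-limited linescans along
# each domain on multiple z-planes and expressed as a percentage of the
# summed domain intensities.

#' Partition a cell's membrane into polarity domains
#'
#' Membrane voxels within the contact distance of the capillary surface form
#' the capillary domains (one per contact patch, numbered in the arbitrary
#' spatial order of the patch table); of the remaining membrane, voxels touching extracellular
#' space become apical and voxels touching neighbouring cells lateral.
#' Precedence for ambiguous voxels is capillary > apical > lateral (contact
#' proximity overrides; touching open extracellular space marks a luminal
#' surface). Only z-planes where the cell's cross-section exceeds
#' `plane_fraction` of its maximum are analysed, approximating measurement
#' "on multiple z planes" without edge slices.
#'
#' @param cell_labels 3D integer label array.
#' @param capillary_mask 3D logical array.
#' @param patches patch table from [cell_contact_patches()] (or the
#'   ground-truth `contacts` of a synthetic geometry).
#' @param cell_id the cell to partition.
#' @param voxel_size voxel spacing (um).
#' @param contact_distance apposition distance (um).
#' @param plane_fraction minimum cross-section fraction for a plane to be
#'   analysed.
#' @return a `domain_partition`: list with `cell_id`, `domains` (named list
#'   of linear voxel indices), `planes` (z indices analysed), `dim`,
#'   `voxel_size`.
#' @export
partition_membrane <- function(cell_labels, capillary_mask, patches,
                               cell_id, voxel_size,
                               contact_distance = 1.0,
                               plane_fraction = 0.2) {
  d <- dim(cell_labels)
  cell_idx <- which(cell_labels == cell_id)
  if (length(cell_idx) == 0L) {
    stop("unknown cell_id: ", cell_id, call. = FALSE)
  }
  adj <- adjacency_flags(cell_labels)
  membrane <- boundary_mask(cell_labels)
  mem_idx <- cell_idx[membrane[cell_idx]]

  # capillary domains = this cell's contact patches, largest first
  vox_list <- attr(patches, "voxels")
  rows <- which(patches$cell_id == cell_id)
  rows <- rows[order(patches$patch_id[rows])]
  domains <- list()
  cap_idx <- integer(0)
  for (r in seq_along(rows)) {
    pv <- vox_list[[rows[r]]]
    domains[[paste0("capillary_", r)]] <- pv
    cap_idx <- c(cap_idx, pv)
  }
  rest <- setdiff(mem_idx, cap_idx)
  is_apical <- adj$bg[rest]
  domains$apical <- rest[is_apical]
  domains$lateral <- rest[!is_apical]

  # plane selection: cross-section above plane_fraction of the maximum
  k_cell <- index_to_ijk(cell_idx, d)[, 3]
  sec <- tabulate(k_cell, nbins = d[3])
  planes <- which(sec >= plane_fraction * max(sec))
  domains <- lapply(domains, function(ix) {
    ix[index_to_ijk(ix, d)[, 3] %in% planes]
  })
  structure(list(cell_id = cell_id, domains = domains, planes = planes,
                 dim = d, voxel_size = voxel_size),
            class = "domain_partition")
}

#' Linescan mean intensity per membrane domain
#'
#' Reproduces the two-stage linescan average: per z-plane, the mean channel
#' intensity over the domain path dilated in-plane to a width of
#' `width_px` pixels; then the unweighted mean of the plane values. Planes
#' where the domain is absent contribute nothing; a domain absent from all
#' planes is reported `NA` (absent, not zero).
#'
#' @param channel 3D intensity array.
#' @param partition a `domain_partition`.
#' @param width_px linescan width in pixels (odd, >= 1; default 5).
#' @return named numeric vector of per-domain mean intensities.
#' @export
linescan_domain_intensity <- function(channel, partition, width_px = 5) {
  stopifnot(inherits(partition, "domain_partition"))
  if (width_px < 1 || width_px %% 2 == 0) {
    stop("width_px must be odd and >= 1", call. = FALSE)
  }
  d <- partition$dim
  stopifnot(all(dim(channel) == d))
  r <- (width_px - 1) / 2
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2 + 1e-9, , drop = FALSE]

  vapply(partition$domains, function(ix) {
    if (length(ix) == 0L) return(NA_real_)
    ijk <- index_to_ijk(ix, d)
    plane_means <- vapply(split(seq_len(nrow(ijk)), ijk[, 3]), function(sel) {
      ij <- ijk[sel, , drop = FALSE]
      # dilate the path to the linescan width within the plane
      px <- outer(ij[, 1], offs$dx, "+")
      py <- outer(ij[, 2], offs$dy, "+")
      ok <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2]
      lin <- unique(px[ok] + d[1] * (py[ok] - 1L) +
                      d[1] * d[2] * (ij[1, 3] - 1L))
      mean(channel[lin])
    }, 0.0)
    mean(plane_means)   # unweighted over planes
  }, 0.0)
}

#' Express per-domain intensities as percentages of their total
#'
#' @param means named per-domain mean intensities (NAs = absent domains).
#' @return named percentages over present domains, summing to 100; all-`NA`
#'   or zero-total input gives `NA`s (undefined, reported missing).
#' @export
percent_of_total <- function(means) {
  out <- rep(NA_real_, length(means))
  names(out) <- names(means)
  present <- !is.na(means)
  if (sum(present) < 2L) return(out)
  total <- sum(means[present])
  if (total <= 0) return(out)
  out[present] <- 100 * means[present] / total
  out
}

#' Polarity profiles for a set of cells
#'
#' Runs [partition_membrane()], [linescan_domain_intensity()] and
#' [percent_of_total()] for every requested cell and channel. By default
#' profiles the cells with exactly two capillary contacts, the population
#' whose polarity the basal/lateral/apical analysis addresses.
#'
#' @param geometry a packed `islet_geometry`.
#' @param channels named list of 3D intensity arrays (e.g. from
#'   [render_channels()]).
#' @param patches patch table; defaults to the geometry's ground truth.
#' @param cell_ids cells to profile; default all two-contact cells.
#' @param width_px linescan width (pixels).
#' @return data frame: `cell_id`, `channel`, `domain`, `mean_intensity`,
#'   `percent`.
#' @export
cell_polarity_profiles <- function(geometry, channels, patches = NULL,
                                   cell_ids = NULL, width_px = 5) {
  stopifnot(inherits(geometry, "islet_geometry"))
  patches <- patches %||% geometry$contacts
  if (is.null(cell_ids)) {
    tab <- table(patches$cell_id)
    cell_ids <- as.integer(names(tab)[tab == 2L])
  }
  capmask <- geometry$labels == LBL_CAP
  out <- list()
  for (cid in cell_ids) {
    part <- partition_membrane(geometry$labels, capmask, patches, cid,
                               geometry$voxel_size)
    for (ch in names(channels)) {
      m <- linescan_domain_intensity(channels[[ch]], part, width_px)
      p <- percent_of_total(m)
      out[[length(out) + 1L]] <- data.frame(
        cell_id = cid, channel = ch, domain = names(m),
        mean_intensity = unname(m), percent = unname(p)
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(cell_id = integer(0), channel = character(0),
                      domain = character(0), mean_intensity = numeric(0),
                      percent = numeric(0)))
  }
  do.call(rbind, out)
}

#' Test domain enrichment across cells
#'
#' One-way ANOVA of per-cell domain percentages across domains, with Tukey
#' HSD pairwise comparisons -- the omnibus + post-hoc design used for
#' linescan polarity data.
#'
#' @param profiles data frame with columns `domain` and `percent` (one row
#'   per cell x domain), e.g. one channel's rows of
#'   [cell_polarity_profiles()].
#' @return list: `F`, `p_value`, `df`, `pairwise` (Tukey table as a data
#'   frame with `comparison`, `diff`, `lwr`, `upr`, `p_adj`), `n_per_domain`.
#' @export
enrichment_test <- function(profiles) {
  df <- profiles[!is.na(profiles$percent), c("domain", "percent")]
  n_dom <- table(df$domain)
  small <- names(n_dom)[n_dom < 2L]
  if (length(small) > 0) {
    warning("excluding domains with <2 observations: ",
            paste(small, collapse = ", "))
    df <- df[!df$domain %in% small, , drop = FALSE]
  }
  if (length(unique(df$domain)) < 2L || nrow(df) < 4L) {
    stop("need >=2 domains with >=2 observations each", call. = FALSE)
  }
  df$domain <- factor(df$domain)
  if (stats::var(df$percent) < 1e-20) {   # all observations identical
    return(list(F = NA_real_, p_value = 1, df = NA,
                pairwise = data.frame(comparison = character(0),
                                      diff = numeric(0), lwr = numeric(0),
                                      upr = numeric(0), p_adj = numeric(0)),
                n_per_domain = table(df$domain)))
  }
  fit <- aov(percent ~ domain, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$domain
  list(
    F = an[1, "F value"], p_value = an[1, "Pr(>F)"],
    df = an[, "Df"],
    pairwise = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL),
    n_per_domain = table(df$domain)
  )
}
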