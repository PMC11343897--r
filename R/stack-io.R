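# TIFF stack I/O with explicit physical calibration. Voxel sizes travel in a
# JSON sidecar (<file>.json) because plain multi-page TIFF carries no
# calibration; reading a stack without a sidecar requires voxel_size
# explicitly -- never a silent default.

#' Write a 3D stack as a multi-page TIFF with a calibration sidecar
#'
#' Label volumes (`type = "label"`) are stored as 16-bit integers (exact for
#' labels up to 65535); intensity volumes (`type = "intensity"`) as 32-bit
#' floats normalised by a scale recorded in the sidecar.
#'
#' @param vol 3D array (integer labels or numeric intensities).
#' @param path output `.tif` path; the sidecar is written to `<path>.json`.
#' @param voxel_size voxel spacing `c(dx, dy, dz)` in micrometres.
#' @param type `"label"` or `"intensity"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path, voxel_size,
                        type = c("intensity", "label")) {
  check_volume(vol)
  type <- match.arg(type)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (type == "label") {
    if (any(vol < 0) || any(vol != round(vol))) {
      stop("label volumes must contain non-negative integers", call. = FALSE)
    }
    if (max(vol) > 65535) stop("label ids exceed 16-bit range", call. = FALSE)
    pages <- lapply(seq_len(dim(vol)[3]), function(k) vol[, , k] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                    compression = "none")
    scale <- 65535
  } else {
    scale <- max(abs(vol), 1e-12)
    pages <- lapply(seq_len(dim(vol)[3]), function(k) vol[, , k] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                    compression = "none")
  }
  meta <- list(voxel_size_um = voxel_size, type = type, scale = scale,
               dim = dim(vol))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' @param path `.tif` path.
#' @param voxel_size required when no `<path>.json` sidecar exists.
#' @return 3D array with attributes `voxel_size` and `type`; label volumes
#'   come back as integer arrays.
#' @export
read_stack <- function(path, voxel_size = NULL) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    NULL
  }
  if (is.null(meta) && is.null(voxel_size)) {
    stop("no calibration: ", path, " has no sidecar and no voxel_size ",
         "was supplied", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vol <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  if (!is.null(meta)) {
    vol <- vol * meta$scale
    if (identical(meta$type, "label")) {
      vol <- array(as.integer(round(vol)), dim = dim(vol))
    }
    attr(vol, "voxel_size") <- meta$voxel_size_um
    attr(vol, "type") <- meta$type
  } else {
    attr(vol, "voxel_size") <- voxel_size
    attr(vol, "type") <- "intensity"
  }
  vol
}
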