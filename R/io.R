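#' Write a calibrated image stack as 16-bit TIFF with a YAML sidecar
#'
#' One channel per file; physical calibration (pixel size, z-step, lesion
#' centre) goes into a sidecar `<path>.yaml` rather than TIFF tags, which
#' are unreliable across writers.
#'
#' @param stack 2D matrix or 3D array of intensities in \[0, 65535\].
#' @param path output TIFF path.
#' @param pixel_size um/pixel.
#' @param z_step um between z-slices.
#' @param lesion_center 0-based `(row, col)` or NULL.
#' @return `path`, invisibly.
#' @export
write_slice_image <- function(stack, path, pixel_size, z_step = 1,
                              lesion_center = NULL) {
  st <- as_stack(stack)
  pages <- lapply(seq_len(dim(st)[3]), function(z)
    round(pmin(pmax(st[, , z], 0), 65535)) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(pixel_size_um = pixel_size, z_step_um = z_step,
               n_z = dim(st)[3],
               lesion_center = if (is.null(lesion_center)) NULL
                 else as.numeric(lesion_center))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a calibrated image stack written by [write_slice_image()]
#'
#' @param path TIFF path (sidecar `<path>.yaml` must exist).
#' @return list with `image` (rows x cols x n_z array, 0-65535 scale),
#'   `pixel_size`, `z_step`, `lesion_center`.
#' @export
read_slice_image <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  st <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (z in seq_along(pages)) st[, , z] <- round(pages[[z]] * 65535)
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) stop("missing calibration sidecar: ", side)
  meta <- yaml::read_yaml(side)
  list(image = st, pixel_size = meta$pixel_size_um,
       z_step = meta$z_step_um,
       lesion_center = if (is.null(meta$lesion_center)) NULL
         else as.numeric(meta$lesion_center))
}
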