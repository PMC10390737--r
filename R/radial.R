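#' Integrated density over a mask
#'
#' Sum of pixel intensities over a region (the ImageJ "integrated density"),
#' plus its area-normalized form, the mean intensity. Normalization by
#' physical area (division by `n * pixel_size^2`) is available via
#' `per_um2 = TRUE`; it differs from the per-pixel form only by the constant
#' `pixel_size^2`.
#'
#' @param image 2D numeric matrix.
#' @param mask logical matrix of the same shape; must select >= 1 pixel.
#' @param pixel_size um/pixel; only used when `per_um2 = TRUE`.
#' @param per_um2 normalize by physical area instead of pixel count.
#' @return list with `integrated`, `normalized`, `n_pixels`.
#' @export
integrated_density <- function(image, mask, pixel_size = 1, per_um2 = FALSE) {
  if (!all(dim(image) == dim(mask))) stop("image and mask shapes differ")
  n <- sum(mask)
  if (n == 0) stop("mask selects no pixels")
  tot <- sum(image[mask])
  area <- if (per_um2) n * pixel_size^2 else n
  list(integrated = tot, normalized = tot / area, n_pixels = n)
}

#' Radial intensity profile over concentric rings
#'
#' Normalized integrated density (mean intensity) per concentric ring centred
#' on the lesion. Rings with no in-image pixels are reported as missing
#' (`NA`), never as zero.
#'
#' @param image 2D numeric matrix (use a projection for stacks).
#' @param geometry a [lesion_geometry()].
#' @param min_coverage rings with in-image coverage below this fraction are
#'   flagged (`included = FALSE`) for downstream exclusion; default 0.5.
#' @return data.frame of class `radial_profile`: `ring`, `inner_um`,
#'   `outer_um`, `mid_um`, `normalized_density`, `integrated`, `n_pixels`,
#'   `coverage`, `included`.
#' @export
radial_profile <- function(image, geometry, min_coverage = 0.5) {
  rings <- build_concentric_rings(geometry, dim(image))
  info <- rings$info
  info$integrated <- NA_real_
  info$normalized_density <- NA_real_
  for (k in seq_along(rings$masks)) {
    if (info$n_pixels[k] > 0) {
      idv <- integrated_density(image, rings$masks[[k]])
      info$integrated[k] <- idv$integrated
      info$normalized_density[k] <- idv$normalized
    }
  }
  info$included <- info$n_pixels > 0 & info$coverage >= min_coverage
  class(info) <- c("radial_profile", "data.frame")
  info
}

#' Area under the radial profile
#'
#' Trapezoidal integral of normalized density against ring midpoint distance
#' in mm (units: intensity x mm). `mode = "index"` integrates against the
#' ring index instead.
#'
#' @param profile a [radial_profile()] result (or any data.frame with
#'   `mid_um` and `normalized_density`).
#' @param mode `"physical"` (default, midpoint distance in mm) or `"index"`.
#' @param use_included drop rings flagged as not included; default TRUE.
#' @return scalar AUC.
#' @export
profile_auc <- function(profile, mode = c("physical", "index"),
                        use_included = TRUE) {
  mode <- match.arg(mode)
  keep <- is.finite(profile$normalized_density)
  if (use_included && "included" %in% names(profile))
    keep <- keep & profile$included
  y <- profile$normalized_density[keep]
  x <- if (mode == "physical") profile$mid_um[keep] / 1000 else
    seq_along(y) - 1
  if (length(y) < 2) stop("AUC needs at least 2 rings with values")
  n <- length(y)
  sum(diff(x) * (y[-n] + y[-1]) / 2)
}

#' Slice outline mask from a fluorescence image
#'
#' Threshold (Otsu) applied to a Gaussian-smoothed copy of the image; used
#' for whole-slice normalized integrated density when no explicit slice mask
#' is supplied.
#'
#' @param image 2D numeric matrix.
#' @param sigma Gaussian smoothing sigma in pixels; default 5.
#' @return logical matrix.
#' @export
slice_mask <- function(image, sigma = 5) {
  rng <- range(image)
  if (diff(rng) == 0) stop("constant image: cannot derive a slice mask")
  sm <- EBImage::gblur(EBImage::Image((image - rng[1]) / diff(rng)),
                       sigma = sigma)
  thr <- EBImage::otsu(sm, range = c(0, 1), levels = 256)
  matrix(as.numeric(sm) > thr, nrow = nrow(image))
}

#' Whole-slice normalized integrated density
#'
#' Integrated density over the slice outline divided by the slice area in
#' pixels. The mask defaults to [slice_mask()] on the image itself.
#'
#' @inheritParams integrated_density
#' @param mask optional explicit slice mask.
#' @return list with `integrated`, `normalized`, `n_pixels`.
#' @export
whole_slice_density <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- slice_mask(image)
  integrated_density(image, mask)
}
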