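#' Lesion-centred concentric geometry
#'
#' Describes the concentric ring scheme used for radial quantification: a
#' lesion centre in 0-based `(row, col)` pixel coordinates, a physical ring
#' spacing (500 um by default, i.e. 0.5 mm), the number of rings and the
#' pixel size.
#'
#' @param center numeric length-2, lesion centre as 0-based `(row, col)`.
#' @param pixel_size pixel edge length in um/pixel (> 0).
#' @param ring_spacing ring width in um (> 0); default 500.
#' @param n_rings number of rings (>= 1). Ring 0 is the central disk.
#' @return an object of class `lesion_geometry`.
#' @export
lesion_geometry <- function(center, pixel_size, ring_spacing = 500, n_rings = 4L) {
  stopifnot(length(center) == 2, is.finite(center))
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.numeric(ring_spacing) || ring_spacing <= 0) stop("ring_spacing must be > 0")
  n_rings <- as.integer(n_rings)
  if (is.na(n_rings) || n_rings < 1L) stop("n_rings must be >= 1")
  structure(
    list(center = as.numeric(center), pixel_size = as.numeric(pixel_size),
         ring_spacing = as.numeric(ring_spacing), n_rings = n_rings),
    class = "lesion_geometry"
  )
}

#' Physical distance of every pixel centre from a reference pixel
#'
#' @param image_shape integer length-2 `(rows, cols)`.
#' @param center 0-based `(row, col)` reference coordinate.
#' @param pixel_size um/pixel.
#' @return matrix of Euclidean distances in um.
#' @export
distance_map_um <- function(image_shape, center, pixel_size) {
  nr <- image_shape[1]; nc <- image_shape[2]
  dr <- (seq_len(nr) - 1) - center[1]
  dc <- (seq_len(nc) - 1) - center[2]
  pixel_size * sqrt(outer(dr^2, dc^2, `+`))
}

#' Build concentric ring masks
#'
#' Ring `k` (0-based) contains the pixels whose centre lies at distance
#' `d` um from the lesion centre with `k * spacing <= d < (k + 1) * spacing`
#' (half-open; ring 0 is the central disk). Masks are clipped to the image;
#' each ring carries its in-image coverage, the ratio of its in-image pixel
#' count to the pixel count expected from the full annulus area.
#'
#' @param geometry a [lesion_geometry()].
#' @param image_shape integer `(rows, cols)`.
#' @return list with `masks` (list of logical matrices) and `info`
#'   (data.frame: `ring`, `inner_um`, `outer_um`, `mid_um`, `n_pixels`,
#'   `coverage`).
#' @export
build_concentric_rings <- function(geometry, image_shape) {
  stopifnot(inherits(geometry, "lesion_geometry"))
  ctr <- geometry$center
  if (ctr[1] < 0 || ctr[2] < 0 || ctr[1] > image_shape[1] - 1 ||
      ctr[2] > image_shape[2] - 1)
    stop("lesion centre lies outside the image")
  d <- distance_map_um(image_shape, ctr, geometry$pixel_size)
  s <- geometry$ring_spacing
  masks <- vector("list", geometry$n_rings)
  info <- data.frame(
    ring = seq_len(geometry$n_rings) - 1L,
    inner_um = (seq_len(geometry$n_rings) - 1) * s,
    outer_um = seq_len(geometry$n_rings) * s
  )
  info$mid_um <- (info$inner_um + info$outer_um) / 2
  npix <- integer(geometry$n_rings)
  for (k in seq_len(geometry$n_rings)) {
    m <- d >= info$inner_um[k] & d < info$outer_um[k]
    masks[[k]] <- m
    npix[k] <- sum(m)
  }
  if (npix[1] == 0) stop("ring 0 is empty: lesion centre outside the image")
  expected <- pi * (info$outer_um^2 - info$inner_um^2) / geometry$pixel_size^2
  info$n_pixels <- npix
  info$coverage <- pmin(1, npix / expected)
  list(masks = masks, info = info)
}

#' Assign a lesion-centred distance to a concentric area
#'
#' Areas follow the half-open 0.5 mm convention: lesion `[0, 500)` um,
#' perilesion `[500, 1000)` um, periphery `>= 1000` um.
#'
#' @param distance_um nonnegative distance(s) in um.
#' @param spacing_um area width in um, default 500.
#' @return factor with levels `lesion`, `perilesion`, `periphery`.
#' @export
assign_region <- function(distance_um, spacing_um = 500) {
  if (any(!is.finite(distance_um)) || any(distance_um < 0))
    stop("distance must be finite and >= 0")
  out <- ifelse(distance_um < spacing_um, "lesion",
                ifelse(distance_um < 2 * spacing_um, "perilesion", "periphery"))
  factor(out, levels = c("lesion", "perilesion", "periphery"))
}
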