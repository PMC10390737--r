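#' Place square ROIs in the concentric areas
#'
#' Default placement when only the lesion centre is known: `rois_per_area`
#' ROIs per concentric area (lesion, perilesion, periphery), centred at the
#' cardinal directions on the annulus mid-radius (250, 750, 1250 um for the
#' 0.5 mm scheme). Explicit ROI coordinates override this placement in
#' [neurite_pipeline()].
#'
#' @param geometry a [lesion_geometry()] (spacing defines the areas).
#' @param image_shape `(rows, cols)` in pixels.
#' @param roi_size_px ROI edge length in pixels.
#' @param rois_per_area ROIs per area; default 4 (cardinal directions;
#'   more cycle through intermediate angles).
#' @return data.frame: `area`, `roi_id`, `row0`, `col0`, `size` (0-based
#'   top-left corner).
#' @export
place_rois <- function(geometry, image_shape, roi_size_px,
                       rois_per_area = 4) {
  s <- geometry$ring_spacing
  mids_um <- c(lesion = 0.5 * s, perilesion = 1.5 * s, periphery = 2.5 * s)
  angles <- 2 * pi * (seq_len(rois_per_area) - 1) / rois_per_area
  out <- list()
  for (a in names(mids_um)) {
    r_px <- mids_um[[a]] / geometry$pixel_size
    for (k in seq_len(rois_per_area)) {
      cr <- geometry$center[1] + r_px * sin(angles[k])
      cc <- geometry$center[2] + r_px * cos(angles[k])
      row0 <- round(cr - roi_size_px / 2)
      col0 <- round(cc - roi_size_px / 2)
      if (row0 < 0 || col0 < 0 || row0 + roi_size_px > image_shape[1] ||
          col0 + roi_size_px > image_shape[2])
        stop(sprintf("ROI %s-%d does not fit inside the image", a, k))
      out[[length(out) + 1L]] <- data.frame(
        area = a, roi_id = sprintf("%s-%d", a, k),
        row0 = row0, col0 = col0, size = roi_size_px)
    }
  }
  res <- do.call(rbind, out)
  res$area <- factor(res$area, levels = c("lesion", "perilesion", "periphery"))
  rownames(res) <- NULL
  res
}

#' Neurite segmentation/skeletonization pipeline
#'
#' Per ROI: background floor subtraction, disk median filter, Li threshold
#' over the ROI z-stack, extended-focus (OR) projection, thinning, and
#' skeleton branch metrics. Area summaries are the means over each area's
#' ROIs; the pooled mean over all ROIs is also returned (the control-slice
#' convention of averaging all 12 ROIs when areas do not differ).
#'
#' A ROI that is constant after floor subtraction (no signal above
#' background) yields zero metrics rather than a threshold error.
#'
#' @param stack 2D matrix or 3D array.
#' @param rois ROI table from [place_rois()] (or any data.frame with
#'   `roi_id`, `area`, `row0`, `col0`, `size`).
#' @param pixel_size um/pixel (0.21 at the default acquisition settings).
#' @param floor background gray floor; default 1200.
#' @param radius median-filter radius in px; default 5.
#' @param per_slice_threshold Li threshold per z-slice instead of pooled.
#' @return list with `per_roi` (data.frame: roi metrics + `area`),
#'   `per_area` (mean metrics by area), `overall` (pooled mean over all
#'   ROIs).
#' @export
neurite_pipeline <- function(stack, rois, pixel_size, floor = 1200,
                             radius = 5, per_slice_threshold = FALSE) {
  st <- as_stack(stack)
  per <- list()
  for (i in seq_len(nrow(rois))) {
    r <- rois[i, ]
    if (r$row0 < 0 || r$col0 < 0 || r$row0 + r$size > dim(st)[1] ||
        r$col0 + r$size > dim(st)[2])
      stop(sprintf("ROI %s lies outside the image", r$roi_id))
    sub <- st[r$row0 + seq_len(r$size), r$col0 + seq_len(r$size), ,
              drop = FALSE]
    sub <- normalize_background(sub, floor = floor)
    sub <- median_filter(sub, radius = radius)
    if (length(unique(as.numeric(sub))) < 2L) {
      met <- data.frame(n_branches = 0L, longest_branch_um = 0,
                        total_length_um = 0, network_density = 0)
    } else {
      bin <- li_threshold(sub, per_slice = per_slice_threshold)$binary
      proj <- extended_focus(bin)
      skel <- skeletonize(proj)
      met <- analyze_skeleton(skel, pixel_size,
                              roi_area_um2 = r$size^2 * pixel_size^2)
    }
    per[[i]] <- cbind(data.frame(roi_id = r$roi_id, area = r$area), met)
  }
  per_roi <- do.call(rbind, per)
  metric_cols <- c("n_branches", "longest_branch_um", "total_length_um",
                   "network_density")
  per_area <- aggregate(per_roi[metric_cols], by = list(area = per_roi$area),
                        FUN = mean)
  overall <- as.data.frame(lapply(per_roi[metric_cols], mean))
  list(per_roi = per_roi, per_area = per_area, overall = overall)
}
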