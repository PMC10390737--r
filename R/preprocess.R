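# Stack convention: a 2D matrix or a 3D array (rows, cols, z).

as_stack <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L))
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a 2D matrix or a 3D (rows, cols, z) array")
}

#' Background floor normalization
#'
#' Subtracts a fixed background gray value and clamps at zero, per pixel and
#' per z-slice: `out = max(in - floor, 0)`. This is the usual reading of
#' "imposing a minimum gray value" in ImageJ workflows; `mode = "clip"`
#' instead raises every pixel below the floor up to it, leaving brighter
#' pixels untouched.
#'
#' @param stack 2D matrix or 3D array, 16-bit-range intensities.
#' @param floor background gray value; default 1200.
#' @param mode `"subtract"` (default) or `"clip"`.
#' @return array of the same shape.
#' @export
normalize_background <- function(stack, floor = 1200,
                                 mode = c("subtract", "clip")) {
  mode <- match.arg(mode)
  if (floor < 0) stop("floor must be >= 0")
  if (mode == "subtract") pmax(stack - floor, 0) else pmax(stack, floor)
}

#' Disk median filter
#'
#' Per-slice 2D median over a disk-shaped neighbourhood of the given radius;
#' image borders are handled by edge replication.
#'
#' @param stack 2D matrix or 3D array.
#' @param radius neighbourhood radius in pixels (>= 1); default 5.
#' @return filtered stack, same shape as the input.
#' @export
median_filter <- function(stack, radius = 5) {
  if (radius < 1) stop("radius must be >= 1")
  was2d <- is.matrix(stack)
  st <- as_stack(stack)
  out <- st
  for (z in seq_len(dim(st)[3]))
    out[, , z] <- cpp_median_disk(st[, , z], as.integer(radius))
  if (was2d) out[, , 1] else out
}

#' Li minimum cross-entropy threshold
#'
#' One global threshold for the whole z-stack (the pooled histogram), by Li's
#' iterative minimum cross-entropy method: from an initial threshold at the
#' image mean, iterate `t <- (mb - mf) / (log(mb) - log(mf))` where `mb`,
#' `mf` are the means of the pixels at or below / above `t`, until successive
#' thresholds differ by less than `tol` gray values. Pixels strictly above
#' the threshold are foreground. Values are shifted to be >= 1 for the
#' logarithms when the stack contains values below 1; the returned threshold
#' is on the original scale. `per_slice = TRUE` thresholds each z-slice
#' independently instead.
#'
#' @param stack 2D matrix or 3D array with at least 2 distinct values.
#' @param tol convergence tolerance in gray values; default 0.5.
#' @param per_slice threshold each slice separately; default FALSE.
#' @return list with `threshold` (scalar, or vector if `per_slice`) and
#'   `binary` (same shape as input, logical-valued array).
#' @export
li_threshold <- function(stack, tol = 0.5, per_slice = FALSE) {
  st <- as_stack(stack)
  if (per_slice) {
    thr <- apply(st, 3, li_threshold_value, tol = tol)
    bin <- st
    for (z in seq_len(dim(st)[3])) bin[, , z] <- st[, , z] > thr[z]
  } else {
    thr <- li_threshold_value(st, tol = tol)
    bin <- st > thr
  }
  if (is.matrix(stack)) bin <- bin[, , 1]
  list(threshold = thr, binary = bin)
}

li_threshold_value <- function(x, tol = 0.5) {
  v <- as.numeric(x)
  if (length(unique(v)) < 2L)
    stop("degenerate input: stack has fewer than 2 distinct values")
  shift <- if (min(v) < 1) 1 - min(v) else 0
  v <- v + shift
  t_cur <- mean(v)
  for (i in 1:500) {
    below <- v <= t_cur
    if (!any(below) || all(below)) break
    mb <- mean(v[below])
    mf <- mean(v[!below])
    t_new <- (mb - mf) / (log(mb) - log(mf))
    if (abs(t_new - t_cur) < tol) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  t_cur - shift
}

#' Extended focus projection of a binary stack
#'
#' A pixel of the 2D output is foreground iff it is foreground in any
#' z-slice (logical OR projection).
#'
#' @param binary_stack logical/0-1 matrix or 3D array.
#' @return logical matrix.
#' @export
extended_focus <- function(binary_stack) {
  st <- as_stack(binary_stack)
  apply(st != 0, c(1, 2), any)
}
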