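#' B-scan image container
#'
#' Wraps a 2D intensity grid with pixel-resolution metadata. Rows index
#' axial depth (row 1 is the shallowest position, depth increases downward)
#' and columns index lateral position; this 1-based convention is used
#' everywhere in the package, including exported files.
#'
#' @param pixels numeric matrix of non-negative intensities, at least 3x3.
#'   Intensities are expected on the normalized `[0, 1]` scale used
#'   throughout the package (image readers normalize 8/16-bit sources).
#' @param axial_res_um axial pixel size in micrometres (> 0).
#' @param lateral_res_um lateral pixel size in micrometres (> 0).
#' @param crop_offset integer `(row, col)` pair recording where this image
#'   sits inside its source frame (`c(0, 0)` for an uncropped image), so
#'   positions measured on a cropped image can be mapped back.
#' @return an object of class `bscan_image`.
#' @export
bscan_image <- function(pixels, axial_res_um, lateral_res_um,
                        crop_offset = c(0L, 0L)) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 3L || ncol(pixels) < 3L)
    stop_invalid("bscan_image: grid must be at least 3x3")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop_invalid("bscan_image: intensities must be finite and >= 0")
  if (!is.numeric(axial_res_um) || axial_res_um <= 0 ||
      !is.numeric(lateral_res_um) || lateral_res_um <= 0)
    stop_invalid("bscan_image: pixel resolutions must be positive")
  crop_offset <- as.integer(crop_offset)
  if (length(crop_offset) != 2L || any(crop_offset < 0L))
    stop_invalid("bscan_image: crop_offset must be two non-negative integers")
  structure(
    list(pixels = pixels, axial_res_um = as.numeric(axial_res_um),
         lateral_res_um = as.numeric(lateral_res_um),
         crop_offset = crop_offset),
    class = "bscan_image")
}

#' @export
print.bscan_image <- function(x, ...) {
  cat(sprintf("<bscan_image> %d rows (axial) x %d cols (lateral), %.3g x %.3g um/px, crop offset (%d, %d)\n",
              nrow(x$pixels), ncol(x$pixels), x$axial_res_um,
              x$lateral_res_um, x$crop_offset[1], x$crop_offset[2]))
  invisible(x)
}

img_height <- function(image) nrow(image$pixels)
img_width <- function(image) ncol(image$pixels)

#' Volume container (ordered stack of B-scans)
#'
#' @param frames list of [bscan_image] objects with identical shape and
#'   resolutions; at least 3 frames.
#' @param slice_gap_um gap between consecutive B-scans in micrometres.
#' @return an object of class `oct_volume`.
#' @export
oct_volume <- function(frames, slice_gap_um) {
  if (!is.list(frames) || length(frames) < 3L)
    stop_invalid("oct_volume: need a list of at least 3 frames",
                 if (length(frames) == 1L) "; use the 2D path (segment_bscan) for a single B-scan" else "")
  ok <- vapply(frames, inherits, logical(1), "bscan_image")
  if (!all(ok)) stop_invalid("oct_volume: all frames must be bscan_image objects")
  dims <- vapply(frames, function(f) dim(f$pixels), integer(2))
  res <- vapply(frames, function(f) c(f$axial_res_um, f$lateral_res_um), numeric(2))
  if (any(dims != dims[, 1]) || any(res != res[, 1]))
    stop_invalid("oct_volume: frames must share shape and resolutions")
  if (!is.numeric(slice_gap_um) || slice_gap_um <= 0)
    stop_invalid("oct_volume: slice_gap_um must be positive")
  structure(list(frames = frames, slice_gap_um = as.numeric(slice_gap_um)),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  f1 <- x$frames[[1]]
  cat(sprintf("<oct_volume> %d frames of %d x %d, slice gap %.3g um\n",
              length(x$frames), nrow(f1$pixels), ncol(f1$pixels),
              x$slice_gap_um))
  invisible(x)
}

#' Boundary curve for one layer interface in a B-scan
#'
#' Per-column axial boundary positions. Columns excluded from processing
#' (e.g. inside a central saturation artifact, or outside the lateral crop)
#' are marked invalid and carry `NA` positions; no number is ever
#' substituted silently.
#'
#' @param positions numeric vector of axial row positions (length = image
#'   width); `NA` where invalid.
#' @param valid logical vector, same length.
#' @param interface_name one of `"anterior"`, `"epithelium_stroma"`,
#'   `"posterior"`, `"other"`.
#' @return an object of class `boundary_curve`.
#' @export
boundary_curve <- function(positions, valid = !is.na(positions),
                           interface_name = "other") {
  positions <- as.numeric(positions)
  valid <- as.logical(valid)
  if (length(valid) != length(positions))
    stop_invalid("boundary_curve: positions and valid must have equal length")
  interface_name <- match.arg(interface_name,
                              c("anterior", "epithelium_stroma", "posterior", "other"))
  positions[!valid] <- NA_real_
  if (any(valid & !is.finite(positions)))
    stop_invalid("boundary_curve: valid positions must be finite")
  structure(list(positions = positions, valid = valid,
                 interface_name = interface_name),
            class = "boundary_curve")
}

#' @export
print.boundary_curve <- function(x, ...) {
  cat(sprintf("<boundary_curve> %s: %d columns, %d valid, axial range [%.2f, %.2f]\n",
              x$interface_name, length(x$positions), sum(x$valid),
              suppressWarnings(min(x$positions, na.rm = TRUE)),
              suppressWarnings(max(x$positions, na.rm = TRUE))))
  invisible(x)
}

#' Boundary surface for one layer interface in a volume
#'
#' @param heights numeric matrix (frame index x column) of axial positions;
#'   `NA` where invalid.
#' @param valid logical matrix, same shape.
#' @param interface_name as in [boundary_curve()].
#' @return an object of class `boundary_surface`.
#' @export
boundary_surface <- function(heights, valid = !is.na(heights),
                             interface_name = "other") {
  heights <- as.matrix(heights)
  storage.mode(heights) <- "double"
  valid <- as.matrix(valid)
  if (!identical(dim(heights), dim(valid)))
    stop_invalid("boundary_surface: heights and valid must share shape")
  interface_name <- match.arg(interface_name,
                              c("anterior", "epithelium_stroma", "posterior", "other"))
  heights[!valid] <- NA_real_
  if (any(valid & !is.finite(heights)))
    stop_invalid("boundary_surface: valid heights must be finite")
  structure(list(heights = heights, valid = valid,
                 interface_name = interface_name),
            class = "boundary_surface")
}

#' @export
print.boundary_surface <- function(x, ...) {
  cat(sprintf("<boundary_surface> %s: %d frames x %d columns, %d valid\n",
              x$interface_name, nrow(x$heights), ncol(x$heights),
              sum(x$valid)))
  invisible(x)
}

#' Fill invalid columns of a boundary curve by linear interpolation
#'
#' Artifact-excluded columns are never interpolated silently by the
#' segmentation itself; this optional post-step bridges interior gaps by
#' linear interpolation between the flanking valid columns. Columns outside
#' the outermost valid columns are left invalid.
#'
#' @param curve a [boundary_curve].
#' @return a [boundary_curve] with interior gaps filled and marked valid.
#' @export
fill_gaps <- function(curve) {
  stopifnot(inherits(curve, "boundary_curve"))
  v <- which(curve$valid)
  if (length(v) < 2L) return(curve)
  inner <- seq(min(v), max(v))
  pos <- curve$positions
  pos[inner] <- stats::approx(v, curve$positions[v], xout = inner)$y
  val <- curve$valid
  val[inner] <- TRUE
  boundary_curve(pos, val, curve$interface_name)
}
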