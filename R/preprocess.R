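#' Detect the corneal apex row
#'
#' The apex (topmost point of the cornea) carries more back-scattered light
#' than the region above it, so the row-intensity summation
#' `S(y) = sum_x I(x, y)` rises sharply there. The apex row is the first
#' (shallowest) strict local maximum of `S` that exceeds the mean of `S`;
#' if no interior strict local maximum exceeds the mean, the global argmax
#' of `S` is returned.
#'
#' @param image a [bscan_image].
#' @return integer row index (1-based) of the apex.
#' @export
detect_apex_row <- function(image) {
  stopifnot(inherits(image, "bscan_image"))
  s <- rowSums(image$pixels)
  n <- length(s)
  if (n < 3L) stop_invalid("detect_apex_row: image height must be >= 3")
  interior <- 2:(n - 1L)
  is_max <- s[interior] > s[interior - 1L] & s[interior] > s[interior + 1L]
  cand <- interior[is_max & s[interior] > mean(s)]
  if (length(cand)) cand[1L] else which.max(s)
}

#' Crop a B-scan to the corneal region of interest
#'
#' Keeps `apex_margin_px` rows above the apex and `depth_extent_px` rows
#' below it (derived from typical corneal thickness and the axial
#' resolution when not given explicitly), and removes `side_crop_px`
#' columns from each lateral edge where the SNR is lowest. The crop offset
#' is recorded so positions can be mapped back to source coordinates.
#'
#' @param image a [bscan_image].
#' @param apex_row apex row index from [detect_apex_row()].
#' @param cfg a [seg_config].
#' @return the cropped [bscan_image] with updated `crop_offset`.
#' @export
crop_roi <- function(image, apex_row, cfg = seg_config()) {
  stopifnot(inherits(image, "bscan_image"))
  Y <- img_height(image); X <- img_width(image)
  if (apex_row < 1L || apex_row > Y)
    stop_invalid("crop_roi: apex_row outside image")
  depth <- cfg_depth_extent_px(cfg, image$axial_res_um)
  side <- cfg_side_crop_px(cfg, X)
  r0 <- max(1L, apex_row - cfg$apex_margin_px)
  r1 <- min(Y, apex_row + depth - 1L)
  c0 <- side + 1L
  c1 <- X - side
  if (r1 - r0 + 1L < 3L || c1 - c0 + 1L < 3L)
    stop_invalid("crop_roi: configured margins leave a region smaller than 3x3")
  bscan_image(image$pixels[r0:r1, c0:c1, drop = FALSE],
              image$axial_res_um, image$lateral_res_um,
              crop_offset = image$crop_offset + c(r0 - 1L, c0 - 1L))
}

#' Map cropped-frame positions back to source coordinates
#'
#' @param positions axial row positions measured on a cropped image.
#' @param image the cropped [bscan_image] whose `crop_offset` applies.
#' @return positions in the source frame.
#' @export
uncrop_rows <- function(positions, image) positions + image$crop_offset[1]

#' Suppress horizontal stripe artifacts
#'
#' Bright horizontal stripes spanning the full image width are a system
#' artifact characterized by rows with an elevated mean. Subtracting each
#' row's mean removes them exactly; the zero-mean result is then shifted by
#' a single global offset (the negated global minimum) so intensities stay
#' non-negative while relative contrasts are preserved. Every output row
#' has the same mean, equal to that offset, and the operation is
#' idempotent.
#'
#' @param image a [bscan_image].
#' @return the corrected [bscan_image].
#' @export
remove_horizontal_artifact <- function(image) {
  stopifnot(inherits(image, "bscan_image"))
  centered <- image$pixels - rowMeans(image$pixels)
  out <- pmax(centered - min(centered), 0)
  bscan_image(out, image$axial_res_um, image$lateral_res_um, image$crop_offset)
}

#' Detect the central saturation artifact
#'
#' Strong specular reflection near the apex saturates a few A-scans,
#' visible as a vertical high-intensity stripe. The image is divided into
#' three equal lateral regions; the mean column intensity of the two
#' peripheral thirds gives a reference level mu, and a middle-third column
#' is flagged as contaminated when its mean exceeds
#' `central_artifact_factor * mu`. Flagged columns are excluded from all
#' downstream boundary operations (not repaired).
#'
#' @param image a [bscan_image] with width >= 9.
#' @param cfg a [seg_config].
#' @return a list of class `artifact_report` with elements
#'   `central_columns` (integer indices, in this image's coordinates),
#'   `horizontal_corrected`, `peripheral_mean`, `threshold_used`.
#' @export
detect_central_artifact <- function(image, cfg = seg_config()) {
  stopifnot(inherits(image, "bscan_image"))
  X <- img_width(image)
  if (X < 9L) stop_invalid("detect_central_artifact: image width must be >= 9")
  k <- floor(X / 3)
  peripheral <- c(1:k, (X - k + 1L):X)
  middle <- setdiff(seq_len(X), peripheral)
  colmean <- colMeans(image$pixels)
  mu <- mean(colmean[peripheral])
  thr <- cfg$central_artifact_factor * mu
  flagged <- middle[colmean[middle] > thr]
  structure(list(central_columns = as.integer(flagged),
                 horizontal_corrected = FALSE,
                 peripheral_mean = mu,
                 threshold_used = thr),
            class = "artifact_report")
}

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf("<artifact_report> %d central column(s) flagged (mu = %.4g, threshold = %.4g); horizontal correction: %s\n",
              length(x$central_columns), x$peripheral_mean, x$threshold_used,
              if (isTRUE(x$horizontal_corrected)) "applied" else "not applied"))
  invisible(x)
}

#' Adaptive (Wiener) denoising
#'
#' Local adaptive minimum mean-square-error filtering with a square window:
#' within each window the local mean `m` and variance `v` are estimated,
#' the noise power `s2` is taken as the mean of the local variances over
#' the image, and the output is `m + max(0, v - s2) / v * (I - m)`. Flat
#' regions (low local variance) are smoothed toward the local mean while
#' strong structure is preserved. Constant images pass through unchanged.
#'
#' @param image a [bscan_image].
#' @param cfg a [seg_config]; `wiener_window` sets the window size.
#' @return the denoised [bscan_image].
#' @export
wiener_denoise <- function(image, cfg = seg_config()) {
  stopifnot(inherits(image, "bscan_image"))
  w <- cfg$wiener_window
  x <- image$pixels
  m <- box_filter(x, w)
  v <- pmax(box_filter(x * x, w) - m * m, 0)
  s2 <- mean(v)
  gain <- ifelse(v > s2 & v > 0, (v - s2) / v, 0)
  out <- pmax(m + gain * (x - m), 0)
  bscan_image(out, image$axial_res_um, image$lateral_res_um, image$crop_offset)
}

#' Full preprocessing pipeline for one B-scan
#'
#' Applies, in order: apex detection, ROI cropping, horizontal-artifact
#' removal, central-artifact detection, and adaptive Wiener denoising.
#'
#' @param image a raw [bscan_image].
#' @param cfg a [seg_config].
#' @return a list with elements `image` (the preprocessed, cropped
#'   [bscan_image]), `report` (the `artifact_report`, column indices in
#'   cropped coordinates), and `apex_row` (in source coordinates).
#' @export
preprocess_bscan <- function(image, cfg = seg_config()) {
  apex <- detect_apex_row(image)
  roi <- crop_roi(image, apex, cfg)
  roi <- remove_horizontal_artifact(roi)
  report <- detect_central_artifact(roi, cfg)
  report$horizontal_corrected <- TRUE
  roi <- wiener_denoise(roi, cfg)
  list(image = roi, report = report, apex_row = apex)
}
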