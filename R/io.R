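## File I/O: grayscale PNG/TIFF images, boundary/surface CSV, JSON sidecar.
## All exports state the coordinate convention in a comment header:
## 1-based indices, row 1 at the top, axial depth increasing with row.

csv_header <- "# coordinate convention: 1-based indices; row 1 = shallowest axial position; depth increases with row index"

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Read a grayscale B-scan image (PNG or TIFF)
#'
#' Intensities are normalized to `[0, 1]` regardless of the source bit
#' depth (8- or 16-bit); multi-channel images are averaged to one channel.
#'
#' @param path image file (`.png`, `.tif`, `.tiff`).
#' @param axial_res_um,lateral_res_um pixel resolutions of the scan.
#' @return a [bscan_image].
#' @export
read_bscan <- function(path, axial_res_um, lateral_res_um) {
  m <- read_gray(path)
  bscan_image(m, axial_res_um, lateral_res_um)
}

read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop_invalid("unsupported image format: .", ext))
  if (length(dim(m)) == 3L) m <- apply(m, c(1, 2), mean)
  m
}

#' Write a grayscale image as 16-bit TIFF
#'
#' @param pixels numeric matrix with values in `[0, 1]`.
#' @param path output path.
#' @export
write_gray_tiff <- function(pixels, path) {
  tiff::writeTIFF(clamp(as.matrix(pixels), 0, 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an OCT volume from a multi-page TIFF or a directory of images
#'
#' A directory is read as lexicographically ordered B-scan frames.
#'
#' @param path multi-page TIFF file or directory.
#' @param axial_res_um,lateral_res_um,slice_gap_um scan geometry.
#' @return an [oct_volume].
#' @export
read_volume <- function(path, axial_res_um, lateral_res_um, slice_gap_um) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 3L)
      stop_invalid("read_volume: directory holds fewer than 3 frames")
    mats <- lapply(files, read_gray)
  } else {
    mats <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(mats)) mats <- list(mats)
    mats <- lapply(mats, function(m)
      if (length(dim(m)) == 3L) apply(m, c(1, 2), mean) else m)
  }
  frames <- lapply(mats, bscan_image, axial_res_um = axial_res_um,
                   lateral_res_um = lateral_res_um)
  oct_volume(frames, slice_gap_um)
}

#' Write boundary curves of one B-scan to CSV
#'
#' Long format with columns `column_index, interface_name, axial_position,
#' valid`; positions are written with full precision so a read-back
#' reproduces them bit-identically, and invalid columns carry `NA`.
#'
#' @param curves named list of [boundary_curve] objects (or a
#'   `corneal_seg` result, whose curves are used).
#' @param path output CSV path.
#' @export
write_boundary_csv <- function(curves, path) {
  if (inherits(curves, "corneal_seg")) curves <- curves$curves
  rows <- unlist(lapply(curves, function(cur) {
    sprintf("%d,%s,%s,%s", seq_along(cur$positions), cur$interface_name,
            fmt_num(cur$positions), ifelse(cur$valid, "TRUE", "FALSE"))
  }))
  writeLines(c(csv_header, "column_index,interface_name,axial_position,valid",
               rows), path)
  invisible(path)
}

#' Read boundary curves from CSV
#'
#' @param path CSV written by [write_boundary_csv()].
#' @return named list of [boundary_curve] objects.
#' @export
read_boundary_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#",
                       colClasses = c("integer", "character", "numeric", "logical"))
  out <- lapply(split(d, d$interface_name), function(g) {
    g <- g[order(g$column_index), ]
    boundary_curve(g$axial_position, g$valid, g$interface_name[1])
  })
  out[order(vapply(out, function(cur) {
    p <- cur$positions[cur$valid]
    if (length(p)) mean(p) else Inf
  }, numeric(1)))]
}

#' Write boundary surfaces of a volume to CSV
#'
#' Long format: `frame_index, column_index, interface_name, height, valid`.
#'
#' @param surfaces named list of [boundary_surface] objects (or a
#'   `corneal_seg3d` result).
#' @param path output CSV path.
#' @export
write_surface_csv <- function(surfaces, path) {
  if (inherits(surfaces, "corneal_seg3d")) surfaces <- surfaces$surfaces
  rows <- unlist(lapply(surfaces, function(s) {
    nf <- nrow(s$heights); nc <- ncol(s$heights)
    sprintf("%d,%d,%s,%s,%s",
            rep(seq_len(nf), nc), rep(seq_len(nc), each = nf),
            s$interface_name, fmt_num(as.vector(s$heights)),
            ifelse(as.vector(s$valid), "TRUE", "FALSE"))
  }))
  writeLines(c(csv_header,
               "frame_index,column_index,interface_name,height,valid", rows),
             path)
  invisible(path)
}

#' Read boundary surfaces from CSV
#'
#' @param path CSV written by [write_surface_csv()].
#' @return named list of [boundary_surface] objects.
#' @export
read_surface_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#",
                       colClasses = c("integer", "integer", "character",
                                      "numeric", "logical"))
  lapply(split(d, d$interface_name), function(g) {
    nf <- max(g$frame_index); nc <- max(g$column_index)
    h <- matrix(NA_real_, nf, nc)
    v <- matrix(FALSE, nf, nc)
    h[cbind(g$frame_index, g$column_index)] <- g$height
    v[cbind(g$frame_index, g$column_index)] <- g$valid
    boundary_surface(h, v, g$interface_name[1])
  })
}

#' Write the JSON sidecar of a segmentation run
#'
#' Records the configuration used, the crop offset, the apex row and the
#' artifact report, so any output file can be traced back to its exact
#' processing parameters.
#'
#' @param seg a `corneal_seg` or `corneal_seg3d` result.
#' @param path output JSON path.
#' @export
write_sidecar <- function(seg, path) {
  cfg <- seg$config
  cfg$layers <- lapply(cfg$layers, as.numeric)
  payload <- list(
    coordinate_convention = "1-based; row 1 = shallowest axial position",
    config = cfg[!vapply(cfg, is.null, logical(1))],
    crop_offset = as.integer(seg$crop_offset))
  if (inherits(seg, "corneal_seg")) {
    payload$apex_row <- seg$apex_row
    payload$central_artifact_columns_cropped <- seg$report$central_columns
    payload$shifts_px <- as.list(seg$shifts)
  } else {
    payload$failed_frames <- seg$failed_frames
    payload$shifts_px <- as.list(seg$shifts)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
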