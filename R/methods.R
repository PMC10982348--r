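## S3 methods for segmentation results.

#' @export
print.corneal_seg <- function(x, ...) {
  cat(sprintf("<corneal_seg> %d x %d B-scan, apex row %d, %d interface(s)\n",
              x$height, x$width, x$apex_row, length(x$curves)))
  for (nm in names(x$curves)) {
    cur <- x$curves[[nm]]
    rng <- range(cur$positions, na.rm = TRUE)
    cat(sprintf("  %-18s %4d valid columns, axial range [%g, %g]\n",
                nm, sum(cur$valid), rng[1], rng[2]))
  }
  if (length(x$shifts))
    cat(sprintf("  layer shifts (px): %s\n",
                paste(sprintf("%s = %d", names(x$shifts), x$shifts),
                      collapse = ", ")))
  invisible(x)
}

#' @export
summary.corneal_seg <- function(object, ...) {
  cat(sprintf("Corneal B-scan segmentation (%d x %d)\n", object$height,
              object$width))
  cat(sprintf("Apex row: %d; crop offset (%d, %d)\n", object$apex_row,
              object$crop_offset[1], object$crop_offset[2]))
  ncc <- length(object$report$central_columns)
  cat(sprintf("Central artifact columns flagged: %d\n", ncc))
  print(object)
  invisible(object)
}

#' Long-format data frame of segmented curves
#'
#' @param x a `corneal_seg` result.
#' @param ... unused.
#' @return data frame with `column_index`, `interface_name`,
#'   `axial_position`, `valid`.
#' @export
as.data.frame.corneal_seg <- function(x, ...) {
  do.call(rbind, lapply(x$curves, function(cur) {
    data.frame(column_index = seq_along(cur$positions),
               interface_name = cur$interface_name,
               axial_position = cur$positions,
               valid = cur$valid, row.names = NULL)
  }))
}

#' Plot a B-scan segmentation
#'
#' Draws the (raw) B-scan as a grayscale raster with the segmented
#' interfaces overlaid.
#'
#' @param x a `corneal_seg` result.
#' @param image optional [bscan_image] to draw under the curves (the
#'   segmentation object does not retain pixels).
#' @param ... passed to [graphics::image()].
#' @export
plot.corneal_seg <- function(x, image = NULL, ...) {
  if (!is.null(image)) {
    px <- image$pixels
    graphics::image(x = seq_len(ncol(px)), y = seq_len(nrow(px)),
                    z = t(px)[, rev(seq_len(nrow(px)))],
                    col = grDevices::gray.colors(256, 0, 1),
                    xlab = "lateral (column)", ylab = "axial (row)",
                    useRaster = TRUE, ...)
    yconv <- function(p) nrow(px) + 1 - p
  } else {
    graphics::plot(NULL, xlim = c(1, x$width), ylim = c(x$height, 1),
                   xlab = "lateral (column)", ylab = "axial (row)", ...)
    yconv <- identity
  }
  cols <- c("red", "gold", "green3", "blue")
  for (i in seq_along(x$curves)) {
    cur <- x$curves[[i]]
    graphics::lines(seq_along(cur$positions),
                    yconv(ifelse(cur$valid, cur$positions, NA)),
                    col = cols[(i - 1) %% length(cols) + 1], lwd = 2)
  }
  graphics::legend("bottomright", legend = names(x$curves),
                   col = cols[seq_along(x$curves)], lwd = 2, bty = "n")
  invisible(x)
}

#' @export
print.corneal_seg3d <- function(x, ...) {
  cat(sprintf("<corneal_seg3d> %d frames of %d x %d, %d surface(s)\n",
              x$n_frames, x$height, x$width, length(x$surfaces)))
  for (nm in names(x$surfaces)) {
    s <- x$surfaces[[nm]]
    rng <- range(s$heights, na.rm = TRUE)
    cat(sprintf("  %-18s %5d valid positions, axial range [%g, %g]\n",
                nm, sum(s$valid), rng[1], rng[2]))
  }
  if (length(x$failed_frames))
    cat("  frames masked invalid:", paste(x$failed_frames, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.corneal_seg3d <- function(object, ...) {
  print(object)
  if (length(object$shifts))
    cat(sprintf("Layer shifts (px): %s\n",
                paste(sprintf("%s = %d", names(object$shifts), object$shifts),
                      collapse = ", ")))
  invisible(object)
}

#' Long-format data frame of segmented surfaces
#'
#' @param x a `corneal_seg3d` result.
#' @param ... unused.
#' @export
as.data.frame.corneal_seg3d <- function(x, ...) {
  do.call(rbind, lapply(x$surfaces, function(s) {
    nf <- nrow(s$heights); nc <- ncol(s$heights)
    data.frame(frame_index = rep(seq_len(nf), nc),
               column_index = rep(seq_len(nc), each = nf),
               interface_name = s$interface_name,
               height = as.vector(s$heights),
               valid = as.vector(s$valid), row.names = NULL)
  }))
}

#' Plot a volume segmentation as height maps
#'
#' One filled raster per surface (axial height as colour over the lateral
#' frame-by-column grid).
#'
#' @param x a `corneal_seg3d` result.
#' @param ... passed to [graphics::image()].
#' @export
plot.corneal_seg3d <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, length(x$surfaces)))
  on.exit(graphics::par(op))
  for (nm in names(x$surfaces)) {
    h <- x$surfaces[[nm]]$heights
    graphics::image(x = seq_len(ncol(h)), y = seq_len(nrow(h)), z = t(h),
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "column", ylab = "frame", main = nm, ...)
  }
  invisible(x)
}
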