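#' Mean unsigned surface positioning error (MSPE) between two curves
#'
#' Per-column unsigned axial distance between a segmented and a reference
#' boundary, evaluated over the columns valid in both curves. Errors are
#' computed in pixels; the micrometre value is derived through the axial
#' resolution.
#'
#' @param seg,truth [boundary_curve] objects of equal width.
#' @param axial_res_um axial pixel size (um) used to express the mean in
#'   micrometres.
#' @return an object of class `mspe_result`: list with `mean_px`,
#'   `std_px` (standard deviation across columns), `mean_um`,
#'   `n_columns`, `per_column_errors`.
#' @export
mspe <- function(seg, truth, axial_res_um = 1) {
  stopifnot(inherits(seg, "boundary_curve"), inherits(truth, "boundary_curve"))
  if (length(seg$positions) != length(truth$positions))
    stop_invalid("mspe: curves have different widths")
  both <- seg$valid & truth$valid
  if (!any(both)) stop_invalid("mspe: no columns valid in both curves")
  err <- abs(seg$positions[both] - truth$positions[both])
  new_mspe(err, axial_res_um)
}

#' MSPE between two boundary surfaces
#'
#' Grid analogue of [mspe()]: errors over the (frame, column) positions
#' valid in both surfaces.
#'
#' @param seg,truth [boundary_surface] objects of equal shape.
#' @param axial_res_um axial pixel size (um).
#' @return an `mspe_result` (here `n_columns` counts grid positions).
#' @export
mspe_surface <- function(seg, truth, axial_res_um = 1) {
  stopifnot(inherits(seg, "boundary_surface"),
            inherits(truth, "boundary_surface"))
  if (!identical(dim(seg$heights), dim(truth$heights)))
    stop_invalid("mspe_surface: surfaces have different shapes")
  both <- seg$valid & truth$valid
  if (!any(both)) stop_invalid("mspe_surface: no positions valid in both surfaces")
  err <- abs(seg$heights[both] - truth$heights[both])
  new_mspe(err, axial_res_um)
}

new_mspe <- function(err, axial_res_um) {
  structure(list(mean_px = mean(err),
                 std_px = if (length(err) > 1L) stats::sd(err) else 0,
                 mean_um = mean(err) * axial_res_um,
                 n_columns = length(err),
                 per_column_errors = err),
            class = "mspe_result")
}

#' @export
print.mspe_result <- function(x, ...) {
  cat(sprintf("MSPE: %.3f +/- %.3f px (%.3f um) over %d positions\n",
              x$mean_px, x$std_px, x$mean_um, x$n_columns))
  invisible(x)
}
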