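#' Shift-based estimation of a deeper layer interface
#'
#' Corneal layers share similar boundary profiles, so a deeper interface
#' is first approximated by shifting the refined air-epithelium profile
#' down by the integer offset that maximizes the summed absolute axial
#' gradient along the shifted profile:
#' `mu* = argmax_{mu in S} sum_x |g(x, f(x) + mu)|`,
#' where `S` is a search range derived from typical layer thickness.
#' Columns whose shifted position leaves the image are dropped from the
#' sum (and invalid in the returned curve).
#'
#' @param g a `gradient_field` (or matrix).
#' @param anterior the refined anterior [boundary_curve].
#' @param shift_range integer vector of candidate downward shifts (px).
#' @param interface_name name for the returned curve.
#' @return a list with `curve` (the shifted [boundary_curve]) and
#'   `best_shift` (integer).
#' @export
estimate_layer_by_shift <- function(g, anterior, shift_range,
                                    interface_name = "other") {
  stopifnot(inherits(anterior, "boundary_curve"))
  ag <- abs(gradient_values(g))
  Y <- nrow(ag); X <- ncol(ag)
  vc <- which(anterior$valid)
  if (!length(vc)) stop_invalid("estimate_layer_by_shift: no valid anterior columns")
  base <- as.integer(round(anterior$positions[vc]))
  shift_range <- as.integer(shift_range)
  totals <- vapply(shift_range, function(mu) {
    rows <- base + mu
    inb <- rows >= 1L & rows <= Y
    if (!any(inb)) return(NA_real_)
    sum(ag[cbind(rows[inb], vc[inb])])
  }, numeric(1))
  if (all(is.na(totals)))
    stop_invalid("estimate_layer_by_shift: search range leaves the image for every column")
  if (max(totals, na.rm = TRUE) <= 0)
    stop_invalid("estimate_layer_by_shift: no gradient signal in the search range")
  best <- shift_range[which.max(totals)]
  pos <- anterior$positions + best
  ok <- anterior$valid & !is.na(pos) & round(pos) >= 1 & round(pos) <= Y
  list(curve = boundary_curve(ifelse(ok, pos, NA_real_), ok, interface_name),
       best_shift = best)
}

#' Normalized linear-growth decay profile
#'
#' Per-column decay constants `p(x)` growing linearly with distance from
#' the centre column, normalized to span `[p_min, p_max]`:
#' `p(x) = p_min + (p_max - p_min) |x - center| / max_distance`. Low `p`
#' at the centre makes central refinement lean on many committed
#' neighbours (high-SNR consensus); high `p` at the periphery lets
#' peripheral columns explore the interface more freely, which matters
#' because the cornea is thinner at the centre than at the periphery.
#'
#' @param width number of columns.
#' @param center centre column index.
#' @param p_min,p_max decay endpoints with `0 < p_min <= p_max < 1`.
#' @return numeric vector of length `width`.
#' @export
linear_growth_p_profile <- function(width, center, p_min, p_max) {
  if (p_min <= 0 || p_max >= 1 || p_min > p_max)
    stop_invalid("linear_growth_p_profile: need 0 < p_min <= p_max < 1")
  x <- seq_len(width)
  dist <- abs(x - center)
  maxd <- max(dist)
  if (maxd == 0) return(rep(p_min, width))
  p_min + (p_max - p_min) * dist / maxd
}

#' Two-pass refinement of a deeper layer interface
#'
#' Pass 1 runs the gradient refinement with the linear-growth decay
#' profile, letting peripheral columns explore; because low peripheral
#' SNR then threatens stability, pass 2 re-runs the refinement anchored
#' on the pass-1 result with a constant low decay (`layer_p_min`) for
#' curve smoothing. Deeper interfaces carry no polynomial shape model,
#' so a median filter (window `median_window`) finishes the smoothing.
#' The result is clamped to within `search_radius_px` of the pass-1
#' output at every column.
#'
#' @param g a `gradient_field` (or matrix).
#' @param initial the initial [boundary_curve] (from
#'   [estimate_layer_by_shift()]).
#' @param cfg a [seg_config].
#' @return the refined [boundary_curve].
#' @export
refine_layer <- function(g, initial, cfg = seg_config()) {
  stopifnot(inherits(initial, "boundary_curve"))
  X <- length(initial$positions)
  vc <- which(initial$valid)
  if (!length(vc)) stop_invalid("refine_layer: no valid columns")
  center <- vc[ceiling(length(vc) / 2)]
  pp <- linear_growth_p_profile(X, center, cfg$layer_p_min, cfg$layer_p_max)
  pass1 <- refine_boundary_2d(g, initial, cfg, p_profile = pp)
  pass2 <- refine_boundary_2d(g, pass1, cfg, p = cfg$layer_p_min)
  pos <- median_filter_runs(pass2$positions, pass2$valid, cfg$median_window)
  r <- cfg$search_radius_px
  pos <- clamp(pos, pass1$positions - r, pass1$positions + r)
  boundary_curve(pos, initial$valid, initial$interface_name)
}

## Enforce physical depth ordering: where curves cross, the deeper curve is
## clipped to one pixel below the shallower one.
enforce_noncrossing <- function(curves) {
  if (length(curves) < 2L) return(curves)
  for (i in 2:length(curves)) {
    upper <- curves[[i - 1L]]; lower <- curves[[i]]
    both <- upper$valid & lower$valid
    cross <- both & lower$positions <= upper$positions
    if (any(cross)) {
      pos <- lower$positions
      pos[cross] <- upper$positions[cross] + 1
      curves[[i]] <- boundary_curve(pos, lower$valid, lower$interface_name)
    }
  }
  curves
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_invalid(sprintf("[stage %s] %s", stage, conditionMessage(e)))
  })
}

#' Segment corneal layer interfaces in one B-scan
#'
#' Runs the full 2D pipeline: preprocessing (apex detection, ROI crop,
#' artifact suppression, denoising), coarse anterior estimation via the
#' boundary function, second-order polynomial fitting, gradient-based
#' refinement with geometric decay, Savitzky-Golay smoothing, and, for
#' each configured deeper interface, shift-based estimation followed by
#' two-pass refinement. Curves are returned in depth order in the
#' original (uncropped) image coordinates, reported on the pixel grid
#' (boundary positions are axial row indices); columns removed by the
#' lateral crop or flagged as central-artifact are invalid. Physical
#' non-crossing of interfaces is enforced.
#'
#' @param image a raw [bscan_image].
#' @param cfg a [seg_config].
#' @return an object of class `corneal_seg`: a list with `curves` (named
#'   list of [boundary_curve], anterior first), `curves_subpixel` (the
#'   real-valued smoothed curves before grid rounding), `report`,
#'   `apex_row`, `shifts` (best shift per deeper layer, px), `config`,
#'   `width`, `height`.
#' @export
segment_bscan <- function(image, cfg = seg_config()) {
  stopifnot(inherits(image, "bscan_image"))
  X0 <- img_width(image); Y0 <- img_height(image)
  pre <- run_stage("preprocess", preprocess_bscan(image, cfg))
  roi <- pre$image
  g <- run_stage("gradient", axial_gradient(roi))
  coarse <- run_stage("coarse_anterior", coarse_anterior(roi, pre$report, cfg))
  fitted <- run_stage("fit_parabola", fit_parabola(coarse))
  refined <- run_stage("refine_anterior",
                       refine_boundary_2d(g, fitted$curve, cfg))
  ant <- run_stage("smooth_anterior", smooth_sg(refined, cfg))

  curves <- list(anterior = ant)
  shifts <- integer(0)
  for (nm in names(cfg$layers)) {
    sr <- cfg_shift_range_px(cfg, nm, roi$axial_res_um)
    est <- run_stage(paste0("estimate_", nm),
                     estimate_layer_by_shift(g, ant, sr, nm))
    curves[[nm]] <- run_stage(paste0("refine_", nm),
                              refine_layer(g, est$curve, cfg))
    shifts[nm] <- est$best_shift
  }
  curves <- enforce_noncrossing(curves)

  ## back to source coordinates, on the pixel grid
  off <- roi$crop_offset
  to_original <- function(curve, round_grid = TRUE) {
    pos <- rep(NA_real_, X0)
    val <- rep(FALSE, X0)
    cols <- seq_len(length(curve$positions)) + off[2]
    p <- curve$positions + off[1]
    if (round_grid) p <- round(p)
    pos[cols] <- p
    val[cols] <- curve$valid
    out <- boundary_curve(pos, val, curve$interface_name)
    if (cfg$interp_gaps) out <- fill_gaps(out)
    out
  }
  structure(list(
    curves = lapply(curves, to_original),
    curves_subpixel = lapply(curves, to_original, round_grid = FALSE),
    report = pre$report, apex_row = pre$apex_row, shifts = shifts,
    config = cfg, width = X0, height = Y0,
    crop_offset = off), class = "corneal_seg")
}
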