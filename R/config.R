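#' Segmentation configuration
#'
#' All tunable parameters of the segmentation pipeline. Lengths expressed
#' in micrometres are converted to pixels at run time using the image's
#' axial resolution, so one configuration works across devices with
#' different sampling.
#'
#' @param apex_margin_px rows kept above the detected apex (default 15).
#' @param depth_extent_px rows kept below the apex; `NULL` (default)
#'   derives `ceil(depth_extent_um / axial_res_um)` per image.
#' @param depth_extent_um depth kept below the apex when `depth_extent_px`
#'   is `NULL`; 1500 um safely exceeds corneal thickness including
#'   curvature sag.
#' @param side_crop_px columns removed from each lateral edge; `NULL`
#'   (default) uses `floor(width / 16)` per side.
#' @param central_artifact_factor a middle-third column is flagged as a
#'   central saturation artifact when its mean intensity exceeds this
#'   multiple of the peripheral-third column mean (default 2).
#' @param wiener_window odd window size of the adaptive Wiener denoiser.
#' @param decay_p geometric-decay constant `p` used when refining the
#'   anterior boundary; weight of a committed pixel at distance `d` is
#'   `p * (1 - p)^d`.
#' @param search_radius_px half-width of the axial search window around the
#'   approximated boundary during refinement (default 5).
#' @param sg_order,sg_window Savitzky-Golay polynomial order and odd window
#'   length for anterior curve smoothing (defaults 1 and 21).
#' @param layer_p_min,layer_p_max endpoints of the normalized linear-growth
#'   decay profile used for deeper-layer refinement: `p` is `layer_p_min`
#'   at the image centre and grows linearly to `layer_p_max` at the edges,
#'   so peripheral columns explore more freely. `layer_p_min` is also the
#'   constant low `p` of the second smoothing pass.
#' @param layers named list of deeper interfaces to segment; each element
#'   is a `c(min, max)` axial shift range in micrometres below the anterior
#'   surface searched by the shift estimator.
#' @param pair_sep_um `c(min, max)` plausible axial separation (um) between
#'   the two boundary pixels of a candidate pair in the coarse anterior
#'   search; derived from corneal thickness.
#' @param candidate_rel_thresh minimum prominence of a candidate local
#'   maximum, as a fraction of the A-scan's dynamic range, required to
#'   enter the pair search (the "strongest response near the boundary"
#'   prior; prominence separates genuine interface bands from speckle
#'   jitter and is invariant to additive intensity offsets); set to 0 to
#'   disable.
#' @param median_window odd window of the median filter applied to refined
#'   deeper-layer curves (no polynomial model is assumed for them).
#' @param median3d_window odd window of the median filter applied to
#'   refined surface height maps.
#' @param smooth3d_gradient logical; optionally pre-smooth the gradient
#'   volume with a 3x3x3 median before 3D refinement (default `FALSE`).
#' @param lateral_decay_radius city-block lateral radius within which
#'   already-refined surface positions contribute decay-weighted support
#'   during 3D refinement.
#' @param weight_trunc decay weights below `weight_trunc * p` are dropped
#'   from refinement sums (geometric tails are negligible; keeps cost
#'   linear in width).
#' @param interp_gaps logical; if `TRUE`, artifact-excluded interior
#'   columns of final curves are filled by linear interpolation
#'   ([fill_gaps()]); default `FALSE` (they stay invalid).
#' @param rng_seed integer seed recorded with runs for reproducibility
#'   (the segmentation itself is deterministic).
#' @return an object of class `seg_config`.
#' @export
seg_config <- function(apex_margin_px = 15L,
                       depth_extent_px = NULL,
                       depth_extent_um = 1500,
                       side_crop_px = NULL,
                       central_artifact_factor = 2,
                       wiener_window = 5L,
                       decay_p = 0.5,
                       search_radius_px = 5L,
                       sg_order = 1L,
                       sg_window = 21L,
                       layer_p_min = 0.3,
                       layer_p_max = 0.9,
                       layers = list(epithelium_stroma = c(30, 120),
                                     posterior = c(300, 1200)),
                       pair_sep_um = c(300, 1200),
                       candidate_rel_thresh = 0.2,
                       median_window = 5L,
                       median3d_window = 3L,
                       smooth3d_gradient = FALSE,
                       lateral_decay_radius = 8L,
                       weight_trunc = 1e-6,
                       interp_gaps = FALSE,
                       rng_seed = 1L) {
  cfg <- list(apex_margin_px = as.integer(apex_margin_px),
              depth_extent_px = if (!is.null(depth_extent_px)) as.integer(depth_extent_px),
              depth_extent_um = depth_extent_um,
              side_crop_px = if (!is.null(side_crop_px)) as.integer(side_crop_px),
              central_artifact_factor = central_artifact_factor,
              wiener_window = as.integer(wiener_window),
              decay_p = decay_p,
              search_radius_px = as.integer(search_radius_px),
              sg_order = as.integer(sg_order),
              sg_window = as.integer(sg_window),
              layer_p_min = layer_p_min,
              layer_p_max = layer_p_max,
              layers = layers,
              pair_sep_um = pair_sep_um,
              candidate_rel_thresh = candidate_rel_thresh,
              median_window = as.integer(median_window),
              median3d_window = as.integer(median3d_window),
              smooth3d_gradient = isTRUE(smooth3d_gradient),
              lateral_decay_radius = as.integer(lateral_decay_radius),
              weight_trunc = weight_trunc,
              interp_gaps = isTRUE(interp_gaps),
              rng_seed = as.integer(rng_seed))
  validate_seg_config(cfg)
  structure(cfg, class = "seg_config")
}

validate_seg_config <- function(cfg) {
  with(cfg, {
    if (apex_margin_px < 0L) stop_invalid("seg_config: apex_margin_px must be >= 0")
    if (!is.null(depth_extent_px) && depth_extent_px <= 0L)
      stop_invalid("seg_config: depth_extent_px must be > 0")
    if (!is.null(side_crop_px) && side_crop_px < 0L)
      stop_invalid("seg_config: side_crop_px must be >= 0")
    if (central_artifact_factor <= 1)
      stop_invalid("seg_config: central_artifact_factor must exceed 1")
    if (!is_odd(wiener_window) || wiener_window < 3L)
      stop_invalid("seg_config: wiener_window must be odd and >= 3")
    if (decay_p <= 0 || decay_p >= 1)
      stop_invalid("seg_config: decay_p must lie in (0, 1)")
    if (search_radius_px < 0L)
      stop_invalid("seg_config: search_radius_px must be >= 0")
    if (!is_odd(sg_window) || sg_window <= sg_order)
      stop_invalid("seg_config: sg_window must be odd and exceed sg_order")
    if (layer_p_min <= 0 || layer_p_max >= 1 || layer_p_min > layer_p_max)
      stop_invalid("seg_config: need 0 < layer_p_min <= layer_p_max < 1")
    if (length(pair_sep_um) != 2L || pair_sep_um[1] <= 0 ||
        pair_sep_um[1] > pair_sep_um[2])
      stop_invalid("seg_config: pair_sep_um must be an increasing positive interval")
    for (nm in names(layers)) {
      s <- layers[[nm]]
      if (length(s) != 2L || s[1] <= 0 || s[1] > s[2])
        stop_invalid("seg_config: layer shift range for '", nm,
                     "' must be a positive increasing interval (layers lie strictly below the anterior)")
    }
    if (!is_odd(median_window) || !is_odd(median3d_window))
      stop_invalid("seg_config: median windows must be odd")
  })
  invisible(cfg)
}

#' @export
print.seg_config <- function(x, ...) {
  cat("<seg_config>\n")
  cat(sprintf("  crop: %d px above apex, %s below, side crop %s\n",
              x$apex_margin_px,
              if (is.null(x$depth_extent_px)) sprintf("%g um", x$depth_extent_um)
              else sprintf("%d px", x$depth_extent_px),
              if (is.null(x$side_crop_px)) "width/16" else sprintf("%d px", x$side_crop_px)))
  cat(sprintf("  artifacts: central factor %.3g; Wiener %dx%d\n",
              x$central_artifact_factor, x$wiener_window, x$wiener_window))
  cat(sprintf("  refinement: p = %.2f, radius %d px, SG order %d window %d\n",
              x$decay_p, x$search_radius_px, x$sg_order, x$sg_window))
  cat(sprintf("  layers: %s\n", paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

## --- derived pixel quantities -------------------------------------------

cfg_depth_extent_px <- function(cfg, axial_res_um) {
  if (!is.null(cfg$depth_extent_px)) cfg$depth_extent_px
  else as.integer(ceiling(cfg$depth_extent_um / axial_res_um))
}

cfg_side_crop_px <- function(cfg, width) {
  if (!is.null(cfg$side_crop_px)) cfg$side_crop_px
  else as.integer(floor(width / 16))
}

cfg_pair_sep_px <- function(cfg, axial_res_um) {
  c(max(2L, as.integer(ceiling(cfg$pair_sep_um[1] / axial_res_um))),
    as.integer(ceiling(cfg$pair_sep_um[2] / axial_res_um)))
}

cfg_shift_range_px <- function(cfg, layer_name, axial_res_um) {
  s <- cfg$layers[[layer_name]]
  if (is.null(s)) stop_invalid("seg_config: unknown layer '", layer_name, "'")
  seq(max(1L, as.integer(ceiling(s[1] / axial_res_um))),
      as.integer(ceiling(s[2] / axial_res_um)))
}

#' Read a segmentation configuration from a YAML file
#'
#' Field names mirror the arguments of [seg_config()]; absent fields keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return a `seg_config` object.
#' @export
read_seg_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(seg_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_invalid("read_seg_config: unknown fields: ", paste(unknown, collapse = ", "))
  do.call(seg_config, vals)
}
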