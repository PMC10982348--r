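#' Specification of a synthetic corneal OCT phantom
#'
#' Describes a synthetic B-scan (or volume) with known interface geometry:
#' each interface is a quadratic depth profile plus an optional sinusoidal
#' (2D, lateral) or Gaussian-bump (3D) non-polynomial perturbation, a
#' peripheral-thickening term (the cornea is thinner at the centre than at
#' the periphery), an over-exposed bright band at the interface, and
#' tissue fill below it. Multiplicative log-normal speckle, additive
#' Gaussian noise, lateral SNR falloff, and the two artifact types seen in
#' clinical scans (full-width horizontal stripes and central vertical
#' saturation) can be injected. Generation is fully reproducible from
#' `seed`.
#'
#' The boundary position convention matches the segmentation target: the
#' interface sits at the row where the axial forward-difference gradient
#' magnitude peaks — the bright band rises over `band_rise_px` rows to its
#' peak at the interface row and drops to the deeper tissue intensity at
#' the next row. Interface rows are realized on the pixel grid (the
#' continuous depth model is rounded per column before rendering) and the
#' realized rows are reported as ground truth; the continuous model is
#' kept in the `"subpixel"` attribute of each truth curve.
#'
#' @param width,height image size in pixels (columns, rows).
#' @param n_frames number of B-scans for a volume phantom.
#' @param axial_res_um,lateral_res_um,slice_gap_um pixel resolutions.
#' @param interfaces list of interface descriptors, each a list with
#'   `name`, `base_depth_px`, `curv_x` (quadratic coefficient across
#'   columns), `curv_v` (across frames, volumes only), `brightness`
#'   (band peak intensity), `fill_below` (tissue intensity below the
#'   interface, down to the next one).
#' @param background intensity above the first interface (and of the
#'   aqueous below the last when its `fill_below` says so).
#' @param band_rise_px rows over which the band ramps up to its peak.
#' @param perturb_amp,perturb_period amplitude (px) and period (columns)
#'   of a sinusoidal lateral perturbation applied to every interface;
#'   `perturb_amp = 0` gives purely quadratic interfaces.
#' @param bump_amp,bump_sigma_px amplitude and lateral scale of a Gaussian
#'   bump centred in the field (volumes; a non-quadratic perturbation that
#'   a quadratic surface fit cannot absorb).
#' @param peripheral_thickening_px extra depth (px) of the deepest
#'   interface at the lateral edges relative to the centre; intermediate
#'   interfaces scale proportionally to their depth fraction.
#' @param speckle_sigma log-sd of multiplicative mean-one log-normal
#'   speckle applied to the signal (0 disables).
#' @param gaussian_sigma sd of additive Gaussian noise (0 disables).
#' @param peripheral_snr_decay fractional contrast loss at the lateral
#'   edges (0 = none, 0.5 = half contrast at the edge columns).
#' @param horizontal_stripe `NULL` or `c(row, amplitude)`: a full-width
#'   additive stripe artifact.
#' @param central_artifact `NULL` or `list(columns =, amplitude =)`:
#'   additive vertical saturation of the given columns.
#' @param replicate_frames if `TRUE`, a volume repeats frame 1 identically.
#' @param seed RNG seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 256L, height = 400L, n_frames = 1L,
                         axial_res_um = 4, lateral_res_um = 15,
                         slice_gap_um = 20,
                         interfaces = list(
                           list(name = "anterior", base_depth_px = 80,
                                curv_x = 0.0015, curv_v = 0.0008,
                                brightness = 1.00, fill_below = 0.35),
                           list(name = "epithelium_stroma", base_depth_px = 98,
                                curv_x = 0.0016, curv_v = 0.0008,
                                brightness = 0.85, fill_below = 0.30),
                           list(name = "posterior", base_depth_px = 220,
                                curv_x = 0.0017, curv_v = 0.0009,
                                brightness = 0.70, fill_below = 0.05)),
                         background = 0.05,
                         band_rise_px = 3L,
                         perturb_amp = 2, perturb_period = 128,
                         bump_amp = 0, bump_sigma_px = 12,
                         peripheral_thickening_px = 4,
                         speckle_sigma = 0.15,
                         gaussian_sigma = 0,
                         peripheral_snr_decay = 0.5,
                         horizontal_stripe = NULL,
                         central_artifact = NULL,
                         replicate_frames = FALSE,
                         seed = 1L) {
  spec <- as.list(environment())
  if (width < 9L || height < 10L)
    stop_invalid("phantom_spec: image too small")
  if (speckle_sigma < 0 || gaussian_sigma < 0 || peripheral_snr_decay < 0 ||
      peripheral_snr_decay >= 1)
    stop_invalid("phantom_spec: noise/decay parameters out of range")
  if (!length(interfaces)) stop_invalid("phantom_spec: need at least one interface")
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d px, %d frame(s), %d interface(s), speckle sigma %.3g, SNR decay %.3g\n",
              x$width, x$height, x$n_frames, length(x$interfaces),
              x$speckle_sigma, x$peripheral_snr_decay))
  invisible(x)
}

## Continuous interface depth model f_i(u, v) for all interfaces:
## returns matrix (n_interfaces x width) for frame v.
phantom_depths <- function(spec, v = 1) {
  u <- seq_len(spec$width)
  cu <- (spec$width + 1) / 2
  cv <- (spec$n_frames + 1) / 2
  bases <- vapply(spec$interfaces, `[[`, numeric(1), "base_depth_px")
  span <- max(bases) - min(bases)
  fr <- if (span > 0) (bases - min(bases)) / span else rep(0, length(bases))
  sine <- if (spec$perturb_amp != 0)
    spec$perturb_amp * sin(2 * pi * (u - cu) / spec$perturb_period)
  else rep(0, spec$width)
  bump <- if (spec$bump_amp != 0)
    spec$bump_amp * exp(-((u - cu)^2 + (v - cv)^2) / (2 * spec$bump_sigma_px^2))
  else rep(0, spec$width)
  thick_norm <- ((u - cu) / max(abs(u - cu)))^2
  t(vapply(seq_along(spec$interfaces), function(i) {
    it <- spec$interfaces[[i]]
    cvv <- if (!is.null(it$curv_v)) it$curv_v else 0
    it$base_depth_px + it$curv_x * (u - cu)^2 + cvv * (v - cv)^2 +
      sine + bump + spec$peripheral_thickening_px * fr[i] * thick_norm
  }, numeric(spec$width)))
}

## Render one frame given realized (rounded) interface rows (matrix
## n_interfaces x width). Noise-free, artifact-free, full contrast.
render_frame_clean <- function(spec, rows) {
  k <- nrow(rows); X <- spec$width; Y <- spec$height
  rise <- spec$band_rise_px
  if (any(rows[1, ] - rise < 1) || any(rows[k, ] + 1 > Y))
    stop_invalid("phantom: interfaces out of frame")
  if (k > 1 && any(diff(rows) < rise + 2))
    stop_invalid("phantom: interfaces closer than band_rise_px + 2")
  bright <- vapply(spec$interfaces, `[[`, numeric(1), "brightness")
  fill <- vapply(spec$interfaces, `[[`, numeric(1), "fill_below")
  img <- matrix(spec$background, Y, X)
  for (x in seq_len(X)) {
    above <- spec$background
    for (i in seq_len(k)) {
      y <- rows[i, x]
      img[(y - rise + 1):y, x] <- above + (bright[i] - above) * seq_len(rise) / rise
      lo <- y + 1L
      hi <- if (i < k) rows[i + 1L, x] - rise else Y
      if (lo <= hi) img[lo:hi, x] <- fill[i]
      above <- fill[i]
    }
  }
  img
}

## Apply SNR falloff, speckle, additive noise and artifacts; clip to [0,1].
degrade_frame <- function(spec, img) {
  X <- spec$width; Y <- spec$height
  u <- seq_len(X); cu <- (X + 1) / 2
  s <- 1 - spec$peripheral_snr_decay * abs(u - cu) / max(abs(u - cu))
  signal <- sweep(img - spec$background, 2, s, `*`)
  if (spec$speckle_sigma > 0) {
    sig <- spec$speckle_sigma
    signal <- signal * matrix(exp(stats::rnorm(Y * X, -sig^2 / 2, sig)), Y, X)
  }
  out <- spec$background + signal
  if (spec$gaussian_sigma > 0)
    out <- out + matrix(stats::rnorm(Y * X, 0, spec$gaussian_sigma), Y, X)
  if (!is.null(spec$horizontal_stripe))
    out[spec$horizontal_stripe[1], ] <- out[spec$horizontal_stripe[1], ] +
      spec$horizontal_stripe[2]
  if (!is.null(spec$central_artifact))
    out[, spec$central_artifact$columns] <- out[, spec$central_artifact$columns] +
      spec$central_artifact$amplitude
  clamp(out, 0, 1)
}

#' Generate a synthetic 2D B-scan with known ground truth
#'
#' @param spec a [phantom_spec].
#' @return a list with `image` (a [bscan_image]), `truth` (named list of
#'   ground-truth [boundary_curve] objects, each carrying the continuous
#'   depth model in its `"subpixel"` attribute), and `spec`.
#' @export
make_phantom_2d <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    f <- phantom_depths(spec, v = (spec$n_frames + 1) / 2)
    rows <- round(f)
    img <- degrade_frame(spec, render_frame_clean(spec, rows))
    truth <- lapply(seq_along(spec$interfaces), function(i) {
      cur <- boundary_curve(rows[i, ], rep(TRUE, spec$width),
                            spec$interfaces[[i]]$name)
      attr(cur, "subpixel") <- f[i, ]
      cur
    })
    names(truth) <- vapply(spec$interfaces, `[[`, character(1), "name")
    list(image = bscan_image(img, spec$axial_res_um, spec$lateral_res_um),
         truth = truth, spec = spec)
  })
}

#' Generate a synthetic 3D volume with known ground truth
#'
#' Interface depths vary smoothly across frames through the quadratic
#' `curv_v` terms (paraboloid surfaces) plus any configured Gaussian bump;
#' with `replicate_frames = TRUE` frame 1 is repeated identically.
#'
#' @param spec a [phantom_spec] with `n_frames >= 3`.
#' @return a list with `volume` (an [oct_volume]), `truth` (named list of
#'   ground-truth [boundary_surface] objects with `"subpixel"`
#'   attributes), and `spec`.
#' @export
make_phantom_3d <- function(spec = phantom_spec(n_frames = 10L)) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$n_frames < 3L) stop_invalid("make_phantom_3d: need n_frames >= 3")
  with_seed(spec$seed, {
    k <- length(spec$interfaces)
    heights <- lapply(seq_len(k), function(i)
      matrix(NA_real_, spec$n_frames, spec$width))
    sub <- lapply(seq_len(k), function(i)
      matrix(NA_real_, spec$n_frames, spec$width))
    frames <- vector("list", spec$n_frames)
    for (v in seq_len(spec$n_frames)) {
      if (isTRUE(spec$replicate_frames) && v > 1L) {
        frames[[v]] <- frames[[1L]]
        for (i in seq_len(k)) {
          heights[[i]][v, ] <- heights[[i]][1L, ]
          sub[[i]][v, ] <- sub[[i]][1L, ]
        }
        next
      }
      f <- phantom_depths(spec, v = v)
      rows <- round(f)
      img <- degrade_frame(spec, render_frame_clean(spec, rows))
      frames[[v]] <- bscan_image(img, spec$axial_res_um, spec$lateral_res_um)
      for (i in seq_len(k)) {
        heights[[i]][v, ] <- rows[i, ]
        sub[[i]][v, ] <- f[i, ]
      }
    }
    truth <- lapply(seq_len(k), function(i) {
      s <- boundary_surface(heights[[i]],
                            matrix(TRUE, spec$n_frames, spec$width),
                            spec$interfaces[[i]]$name)
      attr(s, "subpixel") <- sub[[i]]
      s
    })
    names(truth) <- vapply(spec$interfaces, `[[`, character(1), "name")
    list(volume = oct_volume(frames, spec$slice_gap_um), truth = truth,
         spec = spec)
  })
}
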