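#' Axial forward-difference gradient field
#'
#' `g(x, y) = (I(x, y + 1) - I(x, y)) / 2` for rows `y < Y`; the last row
#' duplicates the previous row's value (one-sided convention) so the field
#' keeps the image shape and stays finite.
#'
#' @param image a [bscan_image].
#' @return an object of class `gradient_field` with element `values`, a
#'   matrix of the same shape as the image.
#' @export
axial_gradient <- function(image) {
  stopifnot(inherits(image, "bscan_image"))
  px <- image$pixels
  Y <- nrow(px)
  g <- (px[c(2:Y, Y), , drop = FALSE] - px) / 2
  g[Y, ] <- g[Y - 1L, ]
  structure(list(values = g), class = "gradient_field")
}

gradient_values <- function(g) {
  if (inherits(g, "gradient_field")) g$values else as.matrix(g)
}

#' Geometric-distribution decay weights
#'
#' `w(d) = p (1 - p)^d` for `d = 0, 1, 2, ...`: committed boundary pixels
#' influence the pixel currently being refined with exponentially less
#' weight the further away they are. The weights are strictly decreasing
#' and sum to 1 over the full support.
#'
#' @param p decay constant in `(0, 1)`; larger `p` concentrates trust on
#'   the nearest committed pixel.
#' @param n number of weights to return.
#' @return an object of class `decay_weights` with elements `p` and
#'   `weights` (length `n`, distances `0:(n-1)`).
#' @export
geometric_weights <- function(p, n) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop_invalid("geometric_weights: p must lie in (0, 1)")
  if (n < 1L) stop_invalid("geometric_weights: n must be >= 1")
  structure(list(p = p, weights = p * (1 - p)^(0:(n - 1L))),
            class = "decay_weights")
}

## Distance beyond which w(d) < trunc * w(0); always >= 0.
decay_dmax <- function(p, trunc) {
  if (trunc <= 0) return(Inf)
  max(0L, as.integer(ceiling(log(trunc) / log(1 - p))) - 1L)
}

#' Gradient-based refinement of a 2D boundary curve
#'
#' Refines a coarse boundary by center-outward propagation. The search is
#' anchored on the coarse (approximated) boundary: each column may move at
#' most `search_radius_px` rows from it. At the central valid column the
#' refined position is simply the argmax of the absolute axial gradient in
#' that window. Proceeding outward column by column in both directions, a
#' candidate offset `delta` rigidly shifts the previously refined profile
#' up or down and is scored by the absolute gradient at the candidate
#' pixel plus the decay-weighted absolute gradient at all shifted
#' previously-refined pixels on the same side:
#' `score(delta) = |g(x, c(x) + delta)| + sum_j w(d_j) |g(x_j, r(x_j) + delta - delta_j)|`
#' with `w(d) = p (1 - p)^d`, `d_j = |x - x_j| - 1` (so the nearest
#' committed column gets weight `p`), and `delta_j` the committed offset
#' of column `x_j`. Invalid columns are skipped but still counted in the
#' distances. Terms with negligible weight (below `weight_trunc * p`) are
#' truncated, keeping the cost linear in width. The result never departs
#' from the coarse boundary by more than the search radius and contains no
#' randomness.
#'
#' @param g a `gradient_field` (or plain matrix) from [axial_gradient()].
#' @param coarse a [boundary_curve] with >= 1 valid column.
#' @param cfg a [seg_config]; `search_radius_px` and `weight_trunc` apply.
#' @param p constant decay; defaults to `cfg$decay_p`.
#' @param p_profile optional per-column decay constants (length = width)
#'   overriding `p`; the value at the column being refined is used.
#' @return the refined [boundary_curve] (same validity mask).
#' @export
refine_boundary_2d <- function(g, coarse, cfg = seg_config(),
                               p = cfg$decay_p, p_profile = NULL) {
  stopifnot(inherits(coarse, "boundary_curve"))
  ag <- abs(gradient_values(g))
  Y <- nrow(ag); X <- ncol(ag)
  if (length(coarse$positions) != X)
    stop_invalid("refine_boundary_2d: curve width does not match gradient field")
  vc <- which(coarse$valid)
  if (!length(vc)) stop_invalid("refine_boundary_2d: all columns invalid")
  r <- cfg$search_radius_px
  deltas <- -r:r
  base <- as.integer(round(coarse$positions))
  p_at <- function(x) if (is.null(p_profile)) p else p_profile[x]

  ## per-column window scores v[delta, x] = |g| at clamp(base + delta)
  v <- matrix(0, length(deltas), X)
  v[, vc] <- vapply(vc, function(x)
    ag[cbind(clamp(base[x] + deltas, 1L, Y), x)], numeric(length(deltas)))

  seed <- vc[ceiling(length(vc) / 2)]
  refined <- rep(NA_real_, X)
  ## ties: first (shallowest) argmax; a fully flat score (no gradient
  ## signal anywhere in reach) keeps the coarse position rather than
  ## drifting to the window edge
  pick <- function(score) {
    if (diff(range(score)) == 0) 0L else deltas[which.max(score)]
  }
  refined[seed] <- clamp(base[seed] + deltas[which.max(v[, seed])], 1L, Y)

  propagate <- function(side_cols, refined) {
    committed <- seed
    for (x in side_cols) {
      px_ <- p_at(x)
      d <- abs(x - committed) - 1L
      keep <- d <= decay_dmax(px_, cfg$weight_trunc)
      w <- px_ * (1 - px_)^d[keep]
      score <- v[, x]
      if (length(w))
        score <- score + as.vector(v[, committed[keep], drop = FALSE] %*% w)
      refined[x] <- clamp(base[x] + pick(score), 1L, Y)
      committed <- c(x, committed)     # nearest first
    }
    refined
  }
  refined <- propagate(vc[vc > seed], refined)
  refined <- propagate(rev(vc[vc < seed]), refined)
  boundary_curve(refined, coarse$valid, coarse$interface_name)
}

#' Savitzky-Golay smoothing of a boundary curve
#'
#' Local least-squares polynomial smoothing (order `sg_order`, window
#' `sg_window`) applied independently to each contiguous run of valid
#' columns; runs shorter than the window use the largest odd window that
#' fits, and runs too short to smooth are left untouched. Endpoints are
#' handled by the filter's polynomial fit within the terminal window, so
#' an order-1 filter reproduces affine curves exactly.
#'
#' @param curve a [boundary_curve].
#' @param cfg a [seg_config].
#' @return the smoothed [boundary_curve].
#' @export
smooth_sg <- function(curve, cfg = seg_config()) {
  stopifnot(inherits(curve, "boundary_curve"))
  pos <- curve$positions
  for (run in valid_runs(curve$valid)) {
    n <- length(run)
    w <- min(cfg$sg_window, if (is_odd(n)) n else n - 1L)
    if (w >= cfg$sg_order + 2L && w >= 3L)
      pos[run] <- signal::sgolayfilt(pos[run], p = cfg$sg_order, n = w)
  }
  boundary_curve(pos, curve$valid, curve$interface_name)
}
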