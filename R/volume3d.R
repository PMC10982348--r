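#' Weighted least-squares quadratic surface fit
#'
#' Fits `z = a0 + a1 u + a2 v + a3 u^2 + a4 u v + a5 v^2` over lateral
#' coordinates (u = column, v = frame) to pooled boundary points. As in
#' [fit_parabola()], the fit is iteratively reweighted least squares with
#' Tukey bisquare weights plus hard rejection of zero-weight points, so
#' contiguous runs of wrong-interface candidates are discounted; random
#' per-A-scan noise is absorbed into the smooth prior shape.
#'
#' @param u,v,z numeric vectors of equal length (>= 6 points).
#' @param weights optional non-negative fit weights.
#' @return an object of class `quadratic_surface` with `coefficients`
#'   (`a0`..`a5`) and `kept` (logical; `FALSE` for rejected outliers).
#' @export
fit_quadratic_surface <- function(u, v, z, weights = NULL) {
  n <- length(z)
  if (length(u) != n || length(v) != n || n < 6L)
    stop_invalid("fit_quadratic_surface: need >= 6 points with matching lengths")
  if (is.null(weights)) weights <- rep(1, n)
  mu <- mean(u); mv <- mean(v)
  uc <- u - mu; vc <- v - mv
  A <- cbind(1, uc, vc, uc^2, uc * vc, vc^2)
  if (qr(A)$rank < 6L)
    stop_invalid("fit_quadratic_surface: rank-deficient design (degenerate point set)")
  rf <- robust_lsfit(A, z, weights)
  b <- rf$coefficients
  ## expand centred polynomial back to raw (u, v) coordinates
  a3 <- b[4]; a4 <- b[5]; a5 <- b[6]
  a1 <- b[2] - 2 * a3 * mu - a4 * mv
  a2 <- b[3] - 2 * a5 * mv - a4 * mu
  a0 <- b[1] - b[2] * mu - b[3] * mv + a3 * mu^2 + a4 * mu * mv + a5 * mv^2
  co <- stats::setNames(c(a0, a1, a2, a3, a4, a5), paste0("a", 0:5))
  structure(list(coefficients = co, kept = rf$kept),
            class = "quadratic_surface")
}

qsurf_eval <- function(fit, u, v) {
  co <- if (is.list(fit)) fit$coefficients else fit
  co[1] + co[2] * u + co[3] * v + co[4] * u^2 + co[5] * u * v + co[6] * v^2
}

#' Evaluate a quadratic surface on a lateral grid
#'
#' @param fit a `quadratic_surface` (or its coefficient vector).
#' @param n_frames,width grid extent (v in `1:n_frames`, u in `1:width`).
#' @return numeric matrix (frame x column) of heights.
#' @export
evaluate_quadratic_surface <- function(fit, n_frames, width) {
  outer(seq_len(n_frames), seq_len(width),
        function(v, u) qsurf_eval(fit, u, v))
}

#' City-block geodesic ordering of a lateral mask
#'
#' Breadth-first traversal of the valid lateral positions from a seed,
#' where distance is the 4-connected (city-block) path length within the
#' mask. The returned order — increasing distance, ties broken by (frame,
#' column) — is the processing order of the 3D refinement: candidates are
#' committed from the corneal centre outwards. Valid positions that cannot
#' be reached from the seed are reported, never dropped silently.
#'
#' @param valid_mask logical matrix (frame x column).
#' @param seed `c(frame, column)` of the starting position (must be valid).
#' @return a list with `order` (integer matrix, columns `frame`, `column`,
#'   `dist`, sorted) and `unreachable` (integer matrix of valid positions
#'   not connected to the seed).
#' @export
geodesic_order <- function(valid_mask, seed) {
  valid_mask <- as.matrix(valid_mask)
  nf <- nrow(valid_mask); nc <- ncol(valid_mask)
  sv <- seed[1]; su <- seed[2]
  if (sv < 1 || sv > nf || su < 1 || su > nc || !valid_mask[sv, su])
    stop_invalid("geodesic_order: seed must be a valid position")
  dist <- matrix(NA_integer_, nf, nc)
  dist[sv, su] <- 0L
  frontier <- matrix(c(sv, su), 1L)
  d <- 0L
  while (nrow(frontier)) {
    nxt <- NULL
    for (k in seq_len(nrow(frontier))) {
      v0 <- frontier[k, 1]; u0 <- frontier[k, 2]
      for (step in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        v1 <- v0 + step[1]; u1 <- u0 + step[2]
        if (v1 >= 1L && v1 <= nf && u1 >= 1L && u1 <= nc &&
            valid_mask[v1, u1] && is.na(dist[v1, u1])) {
          dist[v1, u1] <- d + 1L
          nxt <- rbind(nxt, c(v1, u1))
        }
      }
    }
    frontier <- if (is.null(nxt)) matrix(integer(0), 0L, 2L) else nxt
    d <- d + 1L
  }
  reached <- which(!is.na(dist) & valid_mask, arr.ind = TRUE)
  ord <- reached[order(dist[reached], reached[, 1], reached[, 2]), , drop = FALSE]
  out <- cbind(frame = ord[, 1], column = ord[, 2], dist = dist[ord])
  unreachable <- which(valid_mask & is.na(dist), arr.ind = TRUE)
  colnames(unreachable) <- c("frame", "column")
  list(order = out, unreachable = unreachable)
}

## Central seed: valid position nearest the lateral centroid of the mask.
central_valid_position <- function(valid_mask) {
  idx <- which(valid_mask, arr.ind = TRUE)
  if (!nrow(idx)) stop_invalid("no valid lateral positions")
  ctr <- colMeans(idx)
  k <- which.min((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  c(idx[k, 1], idx[k, 2])
}

#' Gradient-based refinement of a boundary surface
#'
#' 3D analogue of [refine_boundary_2d()]. Positions are processed in
#' city-block geodesic order from the central valid position; the seed
#' takes the axial `|g|` argmax within `search_radius_px` of the coarse
#' surface, and every subsequent position scores offsets `delta` by the
#' absolute gradient at the candidate pixel plus the decay-weighted
#' absolute gradient at already-refined positions within city-block
#' lateral radius `lateral_decay_radius`, rigidly shifted by `delta`
#' relative to the coarse surface. The decay distance is the geodesic
#' distance difference between the candidate and the committed position
#' (`w(d) = p (1 - p)^d`, `d >= 0`). Unlike the 2D chain, where the
#' total decay mass on one side is bounded by 1, a 2D lateral
#' neighbourhood can hold many committed positions per distance ring, so
#' the support term is normalized by `max(1, sum(w))`: committed
#' consensus can at most tie — never outvote — a full-strength edge under
#' the candidate pixel. Score ties are resolved toward the offset with
#' the stronger own gradient (then toward the smaller offset), so an
#' unambiguous edge always wins. The refined surface never departs
#' from the coarse surface by more than the search radius. The height map
#' is then median-smoothed (`median3d_window` x `median3d_window`).
#'
#' @param gvol 3D array (row x column x frame) of axial gradients, e.g.
#'   stacked [axial_gradient()] fields.
#' @param coarse a [boundary_surface].
#' @param cfg a [seg_config].
#' @param p decay constant; defaults to `cfg$decay_p`.
#' @param median_smooth apply the height-map median filter (default TRUE).
#' @return the refined [boundary_surface].
#' @export
refine_surface_3d <- function(gvol, coarse, cfg = seg_config(),
                              p = cfg$decay_p, median_smooth = TRUE) {
  stopifnot(inherits(coarse, "boundary_surface"))
  ag <- abs(gvol)
  Y <- dim(ag)[1]; X <- dim(ag)[2]; NF <- dim(ag)[3]
  if (!identical(dim(coarse$heights), c(NF, X)))
    stop_invalid("refine_surface_3d: surface shape does not match gradient volume")
  r <- cfg$search_radius_px
  deltas <- -r:r
  nd <- length(deltas)
  base <- round(coarse$heights)
  seed <- central_valid_position(coarse$valid)
  geo <- geodesic_order(coarse$valid, seed)
  ord <- geo$order
  dist <- matrix(NA_integer_, NF, X)
  dist[ord[, c("frame", "column"), drop = FALSE]] <- ord[, "dist"]

  ## |g| lookup for a set of (frame, column) positions shifted by deltas:
  ## returns matrix (npos x ndelta)
  lookup <- function(vs, us, b) {
    rows <- clamp(rep(b, nd) + rep(deltas, each = length(b)), 1, Y)
    idx <- rows + (rep(us, nd) - 1) * Y + (rep(vs, nd) - 1) * Y * X
    matrix(ag[idx], length(b), nd)
  }

  refined <- matrix(NA_real_, NF, X)
  committed <- matrix(FALSE, NF, X)
  dmax <- decay_dmax(p, cfg$weight_trunc)
  R <- cfg$lateral_decay_radius
  ball <- expand.grid(dv = -R:R, du = -R:R)
  ball <- ball[abs(ball$dv) + abs(ball$du) <= R & !(ball$dv == 0 & ball$du == 0), ]

  for (k in seq_len(nrow(ord))) {
    v0 <- ord[k, "frame"]; u0 <- ord[k, "column"]
    own <- as.vector(lookup(v0, u0, base[v0, u0]))
    score <- own
    vs <- ball$dv + v0; us <- ball$du + u0
    ok <- vs >= 1 & vs <= NF & us >= 1 & us <= X
    vs <- vs[ok]; us <- us[ok]
    if (length(vs)) {
      li <- cbind(vs, us)
      sel <- committed[li]
      if (any(sel)) {
        vs <- vs[sel]; us <- us[sel]
        d <- dist[v0, u0] - dist[cbind(vs, us)]
        usekeep <- d >= 0 & d <= dmax
        if (any(usekeep)) {
          vs <- vs[usekeep]; us <- us[usekeep]
          w <- p * (1 - p)^d[usekeep]
          vals <- lookup(vs, us, base[cbind(vs, us)])
          score <- score + as.vector(crossprod(vals, w)) / max(1, sum(w))
        }
      }
    }
    dstar <- if (diff(range(score)) == 0) 0L else {
      tied <- which(score == max(score))
      deltas[tied[which.max(own[tied])]]
    }
    refined[v0, u0] <- clamp(base[v0, u0] + dstar, 1, Y)
    committed[v0, u0] <- TRUE
  }
  if (median_smooth && cfg$median3d_window > 1L) {
    sm <- median_filter2d(refined, cfg$median3d_window)
    sm <- clamp(sm, base - r, base + r)       # stay within the search contract
    refined[coarse$valid] <- sm[coarse$valid]
  }
  boundary_surface(refined, coarse$valid, coarse$interface_name)
}

#' Shift-based estimation of a deeper surface in a volume
#'
#' 3D analogue of [estimate_layer_by_shift()]: the deeper surface is the
#' refined air-epithelium surface shifted down by the offset maximizing
#' the summed absolute gradient over the whole lateral grid
#' (`argmax_{mu in S} sum_{x,y} |g(x, y, f(x, y) + mu)|`); positions
#' shifted out of the volume are dropped from the sum.
#'
#' @param gvol 3D gradient array (row x column x frame).
#' @param anterior_surface the refined anterior [boundary_surface].
#' @param shift_range integer candidate shifts (px).
#' @param interface_name name for the returned surface.
#' @return a list with `surface` and `best_shift`.
#' @export
estimate_layer_3d <- function(gvol, anterior_surface, shift_range,
                              interface_name = "other") {
  stopifnot(inherits(anterior_surface, "boundary_surface"))
  ag <- abs(gvol)
  Y <- dim(ag)[1]; X <- dim(ag)[2]; NF <- dim(ag)[3]
  idx <- which(anterior_surface$valid, arr.ind = TRUE)
  if (!nrow(idx)) stop_invalid("estimate_layer_3d: no valid surface positions")
  base <- round(anterior_surface$heights[idx])
  lin0 <- (idx[, 2] - 1) * Y + (idx[, 1] - 1) * Y * X
  shift_range <- as.integer(shift_range)
  totals <- vapply(shift_range, function(mu) {
    rows <- base + mu
    inb <- rows >= 1 & rows <= Y
    if (!any(inb)) return(NA_real_)
    sum(ag[rows[inb] + lin0[inb]])
  }, numeric(1))
  if (all(is.na(totals)))
    stop_invalid("estimate_layer_3d: search range leaves the volume everywhere")
  if (max(totals, na.rm = TRUE) <= 0)
    stop_invalid("estimate_layer_3d: no gradient signal in the search range")
  best <- shift_range[which.max(totals)]
  h <- anterior_surface$heights + best
  ok <- anterior_surface$valid & !is.na(h) & round(h) >= 1 & round(h) <= Y
  h[!ok] <- NA_real_
  list(surface = boundary_surface(h, ok, interface_name), best_shift = best)
}

## 3x3x3 median pre-smoothing of a gradient volume (optional).
median_filter3d <- function(vol) {
  dims <- dim(vol)
  out <- vol
  idx <- function(i, n) clamp(i, 1L, n)
  shifts <- expand.grid(dr = -1:1, dc = -1:1, df = -1:1)
  stacked <- vapply(seq_len(nrow(shifts)), function(k) {
    as.vector(vol[idx(seq_len(dims[1]) + shifts$dr[k], dims[1]),
                  idx(seq_len(dims[2]) + shifts$dc[k], dims[2]),
                  idx(seq_len(dims[3]) + shifts$df[k], dims[3])])
  }, numeric(length(vol)))
  out[] <- apply(stacked, 1L, stats::median)
  out
}

#' Segment corneal layer surfaces in a 3D volume
#'
#' Direct 3D pipeline: frames are preprocessed independently (with a
#' common axial crop window — minimum top and maximum bottom across
#' frames — so the volume stays rectangular), boundary-function candidate
#' points from every frame are pooled into one weighted quadratic surface
#' fit, the anterior surface is refined by geodesic-ordered propagation,
#' and each configured deeper surface is estimated by the 3D shift search
#' and refined the same way. Surfaces are returned depth-ordered in
#' original volume coordinates on the pixel grid, with non-crossing
#' enforced.
#'
#' @param volume an [oct_volume] (>= 3 frames; for a single B-scan use
#'   [segment_bscan()]).
#' @param cfg a [seg_config].
#' @return an object of class `corneal_seg3d`: list with `surfaces`
#'   (named list of [boundary_surface]), `shifts`, `reports` (per-frame
#'   artifact reports), `failed_frames`, `config`, `n_frames`, `width`,
#'   `height`.
#' @export
segment_volume <- function(volume, cfg = seg_config()) {
  if (inherits(volume, "bscan_image") ||
      (is.list(volume) && !inherits(volume, "oct_volume") && length(volume) == 1L))
    stop_invalid("segment_volume: a single B-scan should be segmented with the 2D path (segment_bscan)")
  stopifnot(inherits(volume, "oct_volume"))
  frames <- volume$frames
  NF <- length(frames)
  Y0 <- img_height(frames[[1]]); X0 <- img_width(frames[[1]])
  res <- frames[[1]]$axial_res_um

  ## common axial crop across frames
  apex <- vapply(frames, detect_apex_row, integer(1))
  depth <- cfg_depth_extent_px(cfg, res)
  side <- cfg_side_crop_px(cfg, X0)
  r0 <- max(1L, min(apex) - cfg$apex_margin_px)
  r1 <- min(Y0, max(apex) + depth - 1L)
  c0 <- side + 1L; c1 <- X0 - side
  if (r1 - r0 + 1L < 3L || c1 - c0 + 1L < 3L)
    stop_invalid("segment_volume: crop margins leave an empty region")
  Yc <- r1 - r0 + 1L; Xc <- c1 - c0 + 1L

  valid <- matrix(TRUE, NF, Xc)
  reports <- vector("list", NF)
  failed <- integer(0)
  gvol <- array(0, c(Yc, Xc, NF))
  pts <- list()
  for (v in seq_len(NF)) {
    fr <- frames[[v]]
    res_v <- tryCatch({
      roi <- bscan_image(fr$pixels[r0:r1, c0:c1, drop = FALSE],
                         fr$axial_res_um, fr$lateral_res_um,
                         crop_offset = c(r0 - 1L, c0 - 1L))
      roi <- remove_horizontal_artifact(roi)
      rep_ <- detect_central_artifact(roi, cfg)
      rep_$horizontal_corrected <- TRUE
      roi <- wiener_denoise(roi, cfg)
      list(roi = roi, report = rep_)
    }, error = function(e) e)
    if (inherits(res_v, "error")) {
      warning(sprintf("segment_volume: frame %d failed preprocessing (%s); masked invalid",
                      v, conditionMessage(res_v)))
      failed <- c(failed, v)
      valid[v, ] <- FALSE
      next
    }
    reports[[v]] <- res_v$report
    valid[v, res_v$report$central_columns] <- FALSE
    gvol[, , v] <- axial_gradient(res_v$roi)$values
    coarse_v <- coarse_anterior(res_v$roi, res_v$report, cfg)
    vc <- which(coarse_v$valid)
    if (length(vc))
      pts[[length(pts) + 1L]] <- cbind(u = vc, v = v, z = coarse_v$positions[vc])
  }
  if (!length(pts)) stop_invalid("segment_volume: no usable anterior candidates")
  if (isTRUE(cfg$smooth3d_gradient)) gvol <- median_filter3d(gvol)

  P <- do.call(rbind, pts)
  qfit <- fit_quadratic_surface(P[, "u"], P[, "v"], P[, "z"])
  coarse_h <- evaluate_quadratic_surface(qfit, NF, Xc)
  coarse_h <- clamp(coarse_h, 1, Yc)
  coarse_surf <- boundary_surface(ifelse(valid, coarse_h, NA_real_), valid,
                                  "anterior")

  surfaces <- list(anterior = refine_surface_3d(gvol, coarse_surf, cfg))
  shifts <- integer(0)
  for (nm in names(cfg$layers)) {
    sr <- cfg_shift_range_px(cfg, nm, res)
    est <- estimate_layer_3d(gvol, surfaces$anterior, sr, nm)
    surfaces[[nm]] <- refine_surface_3d(gvol, est$surface, cfg)
    shifts[nm] <- est$best_shift
  }

  ## non-crossing in depth order
  for (i in seq_along(surfaces)[-1]) {
    up <- surfaces[[i - 1]]; lo <- surfaces[[i]]
    both <- up$valid & lo$valid
    cross <- both & lo$heights <= up$heights
    if (any(cross)) {
      h <- lo$heights
      h[cross] <- up$heights[cross] + 1
      surfaces[[i]] <- boundary_surface(h, lo$valid, lo$interface_name)
    }
  }

  ## original coordinates, pixel grid
  to_original <- function(s) {
    h <- matrix(NA_real_, NF, X0)
    va <- matrix(FALSE, NF, X0)
    h[, c0:c1] <- round(s$heights + (r0 - 1L))
    va[, c0:c1] <- s$valid
    h[!va] <- NA_real_
    boundary_surface(h, va, s$interface_name)
  }
  structure(list(surfaces = lapply(surfaces, to_original),
                 shifts = shifts, reports = reports,
                 failed_frames = failed, config = cfg,
                 n_frames = NF, width = X0, height = Y0,
                 crop_offset = c(r0 - 1L, c0 - 1L)),
            class = "corneal_seg3d")
}
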