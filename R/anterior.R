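#' Strict local maxima of an A-scan intensity profile
#'
#' Candidate boundary pixels are restricted to local intensity maxima
#' along each A-scan. An index `i` qualifies when
#' `profile[i] > profile[i - 1]` and `profile[i] > profile[i + 1]`
#' (strict); a flat run bordered by strictly smaller neighbours on both
#' sides contributes its first index as one candidate, which keeps tie
#' handling deterministic.
#'
#' @param ascan numeric vector of length >= 3.
#' @return sorted integer vector of candidate indices (possibly empty).
#' @export
find_axial_local_maxima <- function(ascan) {
  n <- length(ascan)
  if (n < 3L) stop_invalid("find_axial_local_maxima: profile length must be >= 3")
  r <- rle(as.numeric(ascan))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  inner <- 2:(k - 1L)
  is_max <- r$values[inner] > r$values[inner - 1L] &
    r$values[inner] > r$values[inner + 1L]
  as.integer(starts[inner][is_max])
}

#' Boundary function score of a candidate pixel pair
#'
#' The boundary function `G = T+ - T-` scores a pair of candidate boundary
#' pixels in one A-scan: `T+` is the absolute intensity difference between
#' the two pixels (over-exposure at layer edges makes interfaces stand
#' out), and `T-` is the minimum intensity over all pixels between them
#' (within a layer of similar tissue there is little scattered light, so a
#' genuine inter-boundary interval is dark). The minimum is taken over
#' every pixel in `[y1, y2]`, not only candidate pixels.
#'
#' @param ascan numeric A-scan profile.
#' @param y1,y2 candidate indices with `y1 < y2`.
#' @return the score `G` (may be negative).
#' @export
boundary_function_score <- function(ascan, y1, y2) {
  if (y1 >= y2) stop_invalid("boundary_function_score: need y1 < y2")
  abs(ascan[y1] - ascan[y2]) - min(ascan[y1:y2])
}

#' Coarse estimation of the air-epithelium interface
#'
#' Per A-scan, candidate pairs of local maxima are scored with the
#' boundary function and the anterior position is the top (shallower)
#' pixel of the best pair. Two priors constrain the pair search: (i) the
#' axial separation of a pair must lie in a window derived from plausible
#' corneal thickness (`pair_sep_um` scaled by the axial resolution), and
#' (ii) candidates must be prominent: a candidate peak must rise at least
#' `candidate_rel_thresh` of the A-scan's dynamic range above the deeper
#' of the two valleys separating it from its neighbouring candidates.
#' This implements the observation that the strongest response of the
#' system occurs near the corneal boundary: genuine interface bands rise
#' far above the surrounding tissue, while local maxima born of speckle
#' jitter barely rise above their valleys. Prominence is invariant to the
#' additive re-offset of the horizontal-artifact correction, which brightens
#' globally dark rows and defeats any absolute intensity bar. Ties prefer
#' the pair with the shallower top pixel.
#' Columns flagged in the artifact report, or with fewer than two usable
#' candidates, are marked invalid rather than guessed.
#'
#' @param image a preprocessed [bscan_image].
#' @param report an `artifact_report` for this image (or `NULL`).
#' @param cfg a [seg_config].
#' @return a [boundary_curve] named `"anterior"`.
#' @export
coarse_anterior <- function(image, report = NULL, cfg = seg_config()) {
  stopifnot(inherits(image, "bscan_image"))
  px <- image$pixels
  Y <- nrow(px); X <- ncol(px)
  sep <- cfg_pair_sep_px(cfg, image$axial_res_um)
  excluded <- if (is.null(report)) integer(0) else report$central_columns
  pos <- rep(NA_real_, X)
  for (x in setdiff(seq_len(X), excluded)) {
    profile <- px[, x]
    cand <- find_axial_local_maxima(profile)
    if (cfg$candidate_rel_thresh > 0 && length(cand))
      cand <- cand[candidate_prominence(profile, cand) >
                     cfg$candidate_rel_thresh * diff(range(profile))]
    if (length(cand) < 2L) next
    best <- -Inf
    best_y1 <- NA_integer_
    for (i in seq_len(length(cand) - 1L)) {
      y1 <- cand[i]
      js <- cand[cand - y1 >= sep[1] & cand - y1 <= sep[2]]
      if (!length(js)) next
      cm <- cummin(profile[y1:(max(js))])
      sc <- abs(profile[y1] - profile[js]) - cm[js - y1 + 1L]
      jbest <- which.max(sc)
      if (sc[jbest] > best) {
        best <- sc[jbest]
        best_y1 <- y1
      }
    }
    pos[x] <- best_y1
  }
  boundary_curve(pos, !is.na(pos), "anterior")
}

#' Second-order polynomial fit of a boundary curve
#'
#' Fits `y = a0 + a1 x + a2 x^2` over the valid columns by iteratively
#' reweighted least squares with Tukey bisquare weights, followed by a
#' hard rejection of points receiving zero weight. A redescending
#' M-estimator is used rather than plain rejection because coarse errors
#' are not scattered: when the boundary function locks onto the wrong
#' interface it does so over contiguous low-SNR runs, which tilt an
#' ordinary least-squares fit enough that median-residual rejection keeps
#' them. The fitted polynomial replaces the per-column
#' positions of valid columns, eliminating the effect of random noise in
#' low-SNR A-scans; invalid columns stay invalid.
#'
#' @param curve a [boundary_curve] with >= 3 valid columns.
#' @return a list with `curve` (the fitted [boundary_curve]),
#'   `coefficients` (`a0`, `a1`, `a2`), and `kept` (logical over valid
#'   columns, `FALSE` for rejected outliers).
#' @export
fit_parabola <- function(curve) {
  stopifnot(inherits(curve, "boundary_curve"))
  v <- which(curve$valid)
  if (length(v) < 3L) stop_invalid("fit_parabola: need at least 3 valid columns")
  y <- curve$positions[v]
  xc <- v - mean(v)                       # centring keeps the normal equations well-conditioned
  rf <- robust_lsfit(cbind(1, xc, xc^2), y)
  b <- rf$coefficients
  a2 <- b[3]; a1 <- b[2] - 2 * a2 * mean(v)
  a0 <- b[1] - b[2] * mean(v) + a2 * mean(v)^2
  co <- c(a0 = unname(a0), a1 = unname(a1), a2 = unname(a2))
  pos <- rep(NA_real_, length(curve$positions))
  pos[v] <- polyval2(co, v)
  list(curve = boundary_curve(pos, curve$valid, curve$interface_name),
       coefficients = co, kept = rf$kept)
}

## Tukey bisquare IRLS; returns coefficients of the design-matrix fit and
## a logical `kept` (FALSE where the final weight redescended to zero).
robust_lsfit <- function(A, y, weights = NULL, max_iter = 30L) {
  w0 <- if (is.null(weights)) rep(1, length(y)) else weights
  fit <- stats::lm.wfit(A, y, w0)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  kept <- rep(TRUE, length(y))
  for (it in seq_len(max_iter)) {
    r <- y - as.vector(A %*% co)
    s <- 1.4826 * stats::median(abs(r))
    if (s < 1e-8) break
    u <- r / (4.685 * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < ncol(A)) break
    fit <- stats::lm.wfit(A, y, w * w0)
    co_new <- fit$coefficients
    co_new[is.na(co_new)] <- 0
    kept <- w > 0
    if (max(abs(co_new - co)) < 1e-10) { co <- co_new; break }
    co <- co_new
  }
  ## hard pass: drop zero-weight points entirely and refit on the rest
  if (any(!kept) && sum(kept) >= ncol(A)) {
    fit <- stats::lm.wfit(A[kept, , drop = FALSE], y[kept], w0[kept])
    co <- fit$coefficients
    co[is.na(co)] <- 0
  }
  list(coefficients = co, kept = kept)
}

## Rise of each candidate peak above the deeper of the two valleys
## separating it from its neighbouring candidates (profile ends count as
## valley boundaries).
candidate_prominence <- function(profile, cand) {
  k <- length(cand)
  cuts <- c(1L, cand, length(profile))
  valleys <- vapply(seq_len(k + 1L), function(i)
    min(profile[cuts[i]:cuts[i + 1L]]), numeric(1))
  profile[cand] - pmax(valleys[seq_len(k)], valleys[seq_len(k) + 1L])
}

polyval2 <- function(co, x) co[1] + co[2] * x + co[3] * x^2
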