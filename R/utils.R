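## Internal numeric helpers shared across the pipeline.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_odd <- function(x) x %% 2 == 1

#' @noRd
stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

## Box (moving-average) filter of a matrix with replicate padding.
## Replicate padding keeps constants exactly constant at the borders,
## which the adaptive Wiener filter relies on.
box_filter <- function(m, w) {
  stopifnot(is_odd(w), w >= 1)
  if (w == 1) return(m)
  h <- (w - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  ri <- clamp(seq_len(nr + 2L * h) - h, 1L, nr)
  ci <- clamp(seq_len(nc + 2L * h) - h, 1L, nc)
  p <- m[ri, ci, drop = FALSE]
  ## summed-area table with a zero top row / left column
  sat <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  sat[-1L, -1L] <- t(apply(apply(p, 2L, cumsum), 1L, cumsum))
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  ## window around (i,j) in padded coords spans rows i..i+w-1, cols j..j+w-1
  s <- sat[r1 + w, c1 + w, drop = FALSE] - sat[r1, c1 + w, drop = FALSE] -
    sat[r1 + w, c1, drop = FALSE] + sat[r1, c1, drop = FALSE]
  s / (w * w)
}

## 3x3 (or wxw) median filter of a matrix, replicate padding at borders.
## NA entries are ignored; an all-NA window yields NA.
median_filter2d <- function(m, w = 3L) {
  stopifnot(is_odd(w), w >= 1)
  if (w == 1) return(m)
  h <- (w - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  offs <- expand.grid(dr = -h:h, dc = -h:h)
  stacks <- vapply(seq_len(nrow(offs)), function(k) {
    ri <- clamp(seq_len(nr) + offs$dr[k], 1L, nr)
    ci <- clamp(seq_len(nc) + offs$dc[k], 1L, nc)
    as.vector(m[ri, ci, drop = FALSE])
  }, numeric(nr * nc))
  out <- apply(stacks, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  })
  matrix(out, nr, nc)
}

## Running median over a vector applied per contiguous valid run, window k
## (shrunk to the largest odd length <= run length). Endpoints are kept:
## shrinking-window endpoint medians would move well-placed end columns.
median_filter_runs <- function(x, valid, k = 5L) {
  out <- x
  for (run in valid_runs(valid)) {
    n <- length(run)
    kk <- min(k, if (is_odd(n)) n else n - 1L)
    if (kk >= 3L) out[run] <- stats::runmed(x[run], kk, endrule = "keep")
  }
  out
}

## Indices of maximal contiguous TRUE runs of a logical vector.
valid_runs <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    if (isTRUE(r$values[i])) out[[length(out) + 1L]] <- starts[i]:ends[i]
  }
  out
}

## Deterministic seed scope: run expr with the RNG seeded, restoring the
## caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
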