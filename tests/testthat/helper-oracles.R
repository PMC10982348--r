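## Independent brute-force oracles. These deliberately share no code with
## the implementation paths they check.

## All strict interior local maxima of a profile by direct triple scan
## (profiles are generated with distinct values, so no plateaus).
oracle_local_maxima <- function(p) {
  n <- length(p)
  which(vapply(seq_len(n), function(i)
    i > 1 && i < n && p[i] > p[i - 1] && p[i] > p[i + 1], logical(1)))
}

## Boundary function by direct evaluation.
oracle_boundary_score <- function(ascan, y1, y2) {
  tminus <- Inf
  for (mu in y1:y2) tminus <- min(tminus, ascan[mu])
  abs(ascan[y1] - ascan[y2]) - tminus
}

## Best pair over all candidate local maxima within a separation window;
## ties prefer smaller y1, then smaller y2.
oracle_best_pair <- function(ascan, sep_min, sep_max) {
  cand <- oracle_local_maxima(ascan)
  best <- NULL
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    y1 <- cand[i]; y2 <- cand[j]
    if (y1 < y2 && y2 - y1 >= sep_min && y2 - y1 <= sep_max) {
      g <- oracle_boundary_score(ascan, y1, y2)
      if (is.null(best) || g > best$g) best <- list(y1 = y1, y2 = y2, g = g)
    }
  }
  best
}

## Center-out greedy refinement scored by the printed rule, with the
## neighbour term written in its original form
## |g(x_j, refined_j + delta - delta_j)| (explicit loops throughout).
oracle_refine_2d <- function(ag, base, valid, p, r, trunc = 1e-6) {
  X <- ncol(ag); Y <- nrow(ag)
  pvec <- if (length(p) == 1L) rep(p, X) else p
  vc <- which(valid)
  seed <- vc[ceiling(length(vc) / 2)]
  deltas <- -r:r
  refined <- rep(NA_real_, X)
  look <- function(x, row) ag[min(max(row, 1L), Y), x]
  score_of <- function(x, delta, committed) {
    s <- look(x, base[x] + delta)
    for (j in committed) {
      d <- abs(x - j) - 1L
      w <- pvec[x] * (1 - pvec[x])^d
      if (w >= trunc * pvec[x]) {
        delta_j <- refined[j] - base[j]
        s <- s + w * look(j, refined[j] + delta - delta_j)
      }
    }
    s
  }
  sc <- vapply(deltas, function(d) look(seed, base[seed] + d), numeric(1))
  refined[seed] <- min(max(base[seed] + deltas[which.max(sc)], 1L), Y)
  for (side in list(vc[vc > seed], rev(vc[vc < seed]))) {
    committed <- seed
    for (x in side) {
      sc <- vapply(deltas, score_of, numeric(1), x = x, committed = committed)
      delta_star <- if (diff(range(sc)) == 0) 0L else deltas[which.max(sc)]
      refined[x] <- min(max(base[x] + delta_star, 1L), Y)
      committed <- c(x, committed)
    }
  }
  refined
}

## City-block geodesic distances inside a mask via igraph shortest paths.
oracle_geodesic_igraph <- function(mask, seed) {
  nf <- nrow(mask); nc <- ncol(mask)
  id <- function(v, u) (u - 1L) * nf + v
  edges <- integer(0)
  for (v in seq_len(nf)) for (u in seq_len(nc)) {
    if (!mask[v, u]) next
    if (v < nf && mask[v + 1L, u]) edges <- c(edges, id(v, u), id(v + 1L, u))
    if (u < nc && mask[v, u + 1L]) edges <- c(edges, id(v, u), id(v, u + 1L))
  }
  g <- igraph::make_empty_graph(n = nf * nc, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  d <- igraph::distances(g, v = id(seed[1], seed[2]))[1, ]
  matrix(ifelse(is.finite(d), d, NA_real_), nf, nc)
}

## Greedy 3D surface refinement by direct loops (same rule as
## refine_surface_3d, independent arithmetic path, no median smoothing).
oracle_refine_3d <- function(ag, base, valid, p, r, R_lat = 8L, trunc = 1e-6) {
  Y <- dim(ag)[1]; X <- dim(ag)[2]; NF <- dim(ag)[3]
  geo <- geodesic_order(valid, octseg:::central_valid_position(valid))
  ord <- geo$order
  dist <- matrix(NA_integer_, NF, X)
  dist[ord[, c("frame", "column"), drop = FALSE]] <- ord[, "dist"]
  refined <- matrix(NA_real_, NF, X)
  deltas <- -r:r
  for (k in seq_len(nrow(ord))) {
    v0 <- ord[k, "frame"]; u0 <- ord[k, "column"]
    sc <- numeric(length(deltas))
    own <- numeric(length(deltas))
    for (di in seq_along(deltas)) {
      row <- min(max(base[v0, u0] + deltas[di], 1), Y)
      own[di] <- ag[row, u0, v0]
      supp <- 0; wt <- 0
      if (k > 1L) for (kk in seq_len(k - 1L)) {
        v1 <- ord[kk, "frame"]; u1 <- ord[kk, "column"]
        if (abs(v1 - v0) + abs(u1 - u0) > R_lat) next
        d <- dist[v0, u0] - dist[v1, u1]
        if (d < 0) next
        w <- p * (1 - p)^d
        if (w < trunc * p) next
        row1 <- min(max(base[v1, u1] + deltas[di], 1), Y)
        supp <- supp + w * ag[row1, u1, v1]
        wt <- wt + w
      }
      sc[di] <- own[di] + if (wt > 0) supp / max(1, wt) else 0
    }
    dstar <- if (diff(range(sc)) == 0) 0L else {
      tied <- which(sc == max(sc))
      deltas[tied[which.max(own[tied])]]
    }
    refined[v0, u0] <- min(max(base[v0, u0] + dstar, 1), Y)
  }
  refined
}
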