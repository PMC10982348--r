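test_that("quadratic surface fit reproduces exact surfaces", {
  set.seed(1)
  u <- runif(80, 1, 60); v <- runif(80, 1, 20)
  z <- 5 + 0.1 * u + 0.2 * v + 0.01 * u^2
  fit <- fit_quadratic_surface(u, v, z)
  expect_equal(unname(fit$coefficients), c(5, 0.1, 0.2, 0.01, 0, 0),
               tolerance = 1e-9)
  flat <- fit_quadratic_surface(u, v, rep(9, 80))
  expect_equal(unname(flat$coefficients), c(9, 0, 0, 0, 0, 0),
               tolerance = 1e-9)
})

test_that("quadratic surface fit rejects planted outliers", {
  set.seed(2)
  u <- runif(200, 1, 64); v <- runif(200, 1, 20)
  truth <- 40 + 0.05 * u + 0.1 * v + 0.004 * u^2 + 0.002 * u * v + 0.01 * v^2
  z <- truth
  out_idx <- sample(200, 10)          # 5% gross outliers
  z[out_idx] <- z[out_idx] + 30
  fit <- fit_quadratic_surface(u, v, z)
  expect_lt(max(abs(octseg:::qsurf_eval(fit, u, v) - truth)), 0.5)
})

test_that("degenerate point sets are refused", {
  u <- 1:10
  expect_error(fit_quadratic_surface(u, u, runif(10)), "rank-deficient")
  expect_error(fit_quadratic_surface(1:4, 1:4, 1:4), ">= 6 points")
})

test_that("geodesic ordering reproduces city-block distances", {
  mask <- matrix(TRUE, 3, 3)
  geo <- geodesic_order(mask, c(2, 2))
  d <- matrix(NA_integer_, 3, 3)
  d[geo$order[, c("frame", "column"), drop = FALSE]] <- geo$order[, "dist"]
  expect_identical(d, matrix(c(2L, 1L, 2L, 1L, 0L, 1L, 2L, 1L, 2L), 3, 3))
  expect_identical(nrow(geo$unreachable), 0L)
  ## ties broken by (frame, column) lexicographic order
  same_d <- geo$order[geo$order[, "dist"] == 1, c("frame", "column")]
  expect_identical(order(same_d[, 1], same_d[, 2]), seq_len(nrow(same_d)))
})

test_that("a separating wall leaves the far side reported unreachable", {
  mask <- matrix(TRUE, 5, 5)
  mask[, 3] <- FALSE
  geo <- geodesic_order(mask, c(3, 1))
  expect_identical(nrow(geo$unreachable), 10L)
  expect_true(all(geo$unreachable[, "column"] >= 4))
  expect_error(geodesic_order(mask, c(3, 3)), "seed")
})

test_that("geodesic distances equal shortest paths on random masks", {
  skip_if_not_installed("igraph")
  set.seed(12)
  for (rep in 1:20) {
    mask <- matrix(runif(144) > 0.3, 12, 12)
    seeds <- which(mask, arr.ind = TRUE)
    if (!nrow(seeds)) next
    seed <- seeds[sample(nrow(seeds), 1), ]
    geo <- geodesic_order(mask, seed)
    want <- oracle_geodesic_igraph(mask, seed)
    got <- matrix(NA_real_, 12, 12)
    got[geo$order[, c("frame", "column"), drop = FALSE]] <- geo$order[, "dist"]
    expect_identical(got, want)
  }
})

test_that("3D refinement honours its search contract and degenerate cases", {
  set.seed(3)
  Y <- 40; X <- 10; NF <- 6
  ag <- array(runif(Y * X * NF), c(Y, X, NF))
  h <- matrix(20, NF, X)
  coarse <- boundary_surface(h, matrix(TRUE, NF, X), "anterior")
  r0 <- refine_surface_3d(ag, coarse, seg_config(search_radius_px = 0))
  expect_identical(r0$heights, coarse$heights)
  ref <- refine_surface_3d(ag, coarse, seg_config(search_radius_px = 3))
  expect_true(all(abs(ref$heights - 20) <= 3))
})

test_that("3D greedy refinement matches the explicit-loop oracle", {
  set.seed(23)
  for (rep in 1:5) {
    Y <- 15; X <- 3; NF <- 3
    ag <- array(runif(Y * X * NF), c(Y, X, NF))
    base <- matrix(sample(5:10, NF * X, replace = TRUE), NF, X)
    valid <- matrix(TRUE, NF, X)
    coarse <- boundary_surface(base, valid, "anterior")
    p <- runif(1, 0.3, 0.8)
    got <- refine_surface_3d(ag, coarse, seg_config(search_radius_px = 1),
                             p = p, median_smooth = FALSE)
    want <- oracle_refine_3d(ag, base, valid, p, 1)
    expect_identical(got$heights, want)
  }
})

test_that("3D refinement recovers a non-quadratic bump from a quadratic start", {
  NF <- 8; X <- 24; Y <- 60
  u <- matrix(rep(1:X, each = NF), NF, X)
  v <- matrix(rep(1:NF, X), NF, X)
  truth <- round(30 + 0.01 * (u - 12)^2 + 0.05 * (v - 4)^2 +
                   3 * exp(-((u - 12)^2 + (v - 4)^2) / 18))
  ag <- array(0, c(Y, X, NF))
  for (f in 1:NF) ag[cbind(truth[f, ], 1:X, f)] <- 1
  qfit <- fit_quadratic_surface(as.vector(u), as.vector(v), as.vector(truth))
  coarse_h <- round(evaluate_quadratic_surface(qfit, NF, X))
  expect_true(all(abs(coarse_h - truth) <= 5))   # within reach of the window
  coarse <- boundary_surface(coarse_h, matrix(TRUE, NF, X), "anterior")
  ref <- refine_surface_3d(ag, coarse, seg_config(), median_smooth = FALSE)
  expect_identical(ref$heights, matrix(as.numeric(truth), NF, X))
})

test_that("3D shift estimation finds planted surfaces and rejects zero gradient", {
  NF <- 6; X <- 20; Y <- 100
  base <- matrix(30L, NF, X)
  ag <- array(0, c(Y, X, NF))
  for (f in 1:NF) {
    ag[cbind(base[f, ], 1:X, f)] <- 1
    ag[cbind(base[f, ] + 25L, 1:X, f)] <- 1       # planted deeper surface
    ag[cbind(base[f, ] + 45L, 1:X, f)] <- 0.5     # weaker, deeper one
  }
  ant <- boundary_surface(base, matrix(TRUE, NF, X), "anterior")
  est <- estimate_layer_3d(ag, ant, 15:60, "posterior")
  expect_identical(est$best_shift, 25L)
  expect_equal(est$surface$heights, base + 25)
  expect_error(estimate_layer_3d(array(0, c(Y, X, NF)), ant, 15:60),
               "no gradient signal")
})

test_that("segment_volume refuses a single frame and points to the 2D path", {
  img <- bscan_image(matrix(0.5, 20, 20), 4, 15)
  expect_error(oct_volume(list(img), 20), "2D path|at least 3")
  expect_error(segment_volume(img), "segment_bscan")
})

test_that("segment_volume recovers all surfaces of a mildly speckled volume", {
  ph <- make_phantom_3d(volume_phantom_spec(seed = 11))
  seg <- segment_volume(ph$volume)
  errs <- vapply(names(ph$truth), function(nm)
    mspe_surface(seg$surfaces[[nm]], ph$truth[[nm]])$mean_px, numeric(1))
  expect_lt(max(errs), 2)
  ## depth-ordered, non-crossing
  for (i in 2:length(seg$surfaces)) {
    up <- seg$surfaces[[i - 1]]; lo <- seg$surfaces[[i]]
    both <- up$valid & lo$valid
    expect_true(all(lo$heights[both] > up$heights[both]))
  }
})

test_that("a replicated-frame volume gives near-constant surfaces matching 2D", {
  spec <- volume_phantom_spec(seed = 5, speckle_sigma = 0.05,
                              replicate_frames = TRUE)
  ph <- make_phantom_3d(spec)
  seg3 <- segment_volume(ph$volume)
  seg2 <- segment_bscan(ph$volume$frames[[1]])
  for (nm in names(seg3$surfaces)) {
    s <- seg3$surfaces[[nm]]
    ## constancy along frames: mean absolute deviation from the per-column
    ## median across frames stays sub-pixel
    vc <- which(s$valid[1, ])
    med <- apply(s$heights[, vc, drop = FALSE], 2, median)
    expect_lt(mean(abs(sweep(s$heights[, vc, drop = FALSE], 2, med))), 0.5)
    ## agreement with the 2D segmentation of the replicated frame
    c2 <- seg2$curves[[nm]]
    both <- s$valid[1, ] & c2$valid
    err <- mean(abs(s$heights[1, both] - c2$positions[both]))
    expect_lt(err, 1)
  }
})
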