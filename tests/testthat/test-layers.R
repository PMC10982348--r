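## Gradient field with horizontal edges at anterior + given offsets.
shifted_edge_field <- function(anterior, offsets, X, Y, strengths = NULL) {
  if (is.null(strengths)) strengths <- rep(1, length(offsets))
  ag <- matrix(0, Y, X)
  ag[cbind(anterior, seq_len(X))] <- 1
  for (k in seq_along(offsets))
    ag[cbind(anterior + offsets[k], seq_len(X))] <- strengths[k]
  ag
}

test_that("shift estimation finds a planted deeper interface", {
  X <- 50; Y <- 200
  anterior <- round(30 + 0.002 * (1:X - 25)^2)
  ag <- shifted_edge_field(anterior, 40, X, Y)
  ant <- boundary_curve(anterior, rep(TRUE, X), "anterior")
  est <- estimate_layer_by_shift(ag, ant, 20:60, "posterior")
  expect_identical(est$best_shift, 40L)
  expect_equal(est$curve$positions, anterior + 40)
})

test_that("shift estimation refuses a zero-gradient field", {
  ant <- boundary_curve(rep(30, 20), rep(TRUE, 20))
  expect_error(estimate_layer_by_shift(matrix(0, 100, 20), ant, 10:50),
               "no gradient signal")
})

test_that("the stronger of two planted interfaces wins", {
  X <- 40; Y <- 150
  anterior <- rep(30L, X)
  ag <- shifted_edge_field(anterior, c(30, 50), X, Y, strengths = c(1, 0.5))
  ant <- boundary_curve(anterior, rep(TRUE, X))
  est <- estimate_layer_by_shift(ag, ant, 20:60)
  expect_identical(est$best_shift, 30L)
})

test_that("shift estimation is translation-equivariant", {
  set.seed(6)
  X <- 30; Y <- 120
  anterior <- rep(40L, X)
  ag <- shifted_edge_field(anterior, 25, X, Y) +
    matrix(runif(Y * X, 0, 0.1), Y, X)
  k <- 7L
  ag_shift <- rbind(matrix(0, k, X), ag[1:(Y - k), ])
  ant <- boundary_curve(anterior, rep(TRUE, X))
  ant_shift <- boundary_curve(anterior + k, rep(TRUE, X))
  e1 <- estimate_layer_by_shift(ag, ant, 10:40)
  e2 <- estimate_layer_by_shift(ag_shift, ant_shift, 10:40)
  expect_identical(e1$best_shift, e2$best_shift)
  expect_equal(e2$curve$positions, e1$curve$positions + k)
})

test_that("the linear-growth decay profile spans [p_min, p_max] symmetrically", {
  expect_equal(linear_growth_p_profile(5, 3, 0.2, 0.8),
               c(0.8, 0.5, 0.2, 0.5, 0.8))
  expect_equal(linear_growth_p_profile(7, 4, 0.4, 0.4), rep(0.4, 7))
  for (w in c(9, 20, 51)) {
    ctr <- ceiling(w / 2)
    pp <- linear_growth_p_profile(w, ctr, 0.3, 0.9)
    expect_equal(pp[ctr], 0.3)
    expect_equal(max(pp), 0.9)
    expect_identical(which.min(pp), as.integer(ctr))
  }
  expect_error(linear_growth_p_profile(5, 3, 0.9, 0.3), "p_min")
})

test_that("an initial curve already on a sharp edge is a fixed point of refinement", {
  X <- 80; Y <- 120
  truth <- round(60 + 2 * sin(2 * pi * (1:X) / 30))
  ag <- matrix(0, Y, X)
  ag[cbind(truth, seq_len(X))] <- 1
  init <- boundary_curve(truth, rep(TRUE, X), "posterior")
  out <- refine_layer(ag, init, seg_config())
  expect_identical(out$positions, as.numeric(truth))
})

test_that("two-pass refinement recovers peripheral thickening a rigid shift cannot", {
  ph <- make_phantom_2d(clean_phantom_spec())
  cfg <- seg_config()
  pre <- preprocess_bscan(ph$image, cfg)
  g <- axial_gradient(pre$image)
  cols <- seq_len(ncol(pre$image$pixels)) + pre$image$crop_offset[2]
  off <- pre$image$crop_offset[1]
  ant_true <- ph$truth$anterior$positions[cols] - off
  post_true <- ph$truth$posterior$positions[cols] - off
  ant <- boundary_curve(ant_true, rep(TRUE, length(cols)), "anterior")
  est <- estimate_layer_by_shift(g, ant,
                                 octseg:::cfg_shift_range_px(cfg, "posterior", 4),
                                 "posterior")
  truth_curve <- boundary_curve(post_true, rep(TRUE, length(cols)), "posterior")
  rigid_err <- mspe(est$curve, truth_curve)$mean_px
  refined <- refine_layer(g, est$curve, cfg)
  refined_err <- mspe(refined, truth_curve)$mean_px
  ## the bowl-shaped extra sag defeats a rigid shift but not the refinement
  expect_gt(rigid_err, 0.5)
  expect_lt(refined_err, 1)
  expect_lt(refined_err, rigid_err)
})

test_that("zero-SNR periphery does not run away during layer refinement", {
  X <- 100; Y <- 120
  truth <- rep(60L, X)
  ag <- matrix(0, Y, X)
  inner <- 11:90
  ag[cbind(truth[inner], inner)] <- 1    # outer 10% of columns carry no signal
  init <- boundary_curve(truth, rep(TRUE, X), "posterior")
  out <- refine_layer(ag, init, seg_config())
  r <- seg_config()$search_radius_px
  expect_true(all(abs(out$positions - truth) <= 2 * r))
  ## columns far outside the decay truncation stay exactly on the initial curve
  far <- c(1:3, 98:100)
  expect_identical(out$positions[far], as.numeric(truth[far]))
})

test_that("segment_bscan recovers all interfaces on a mildly speckled phantom", {
  ph <- make_phantom_2d(phantom_spec(seed = 2, speckle_sigma = 0.1,
                                     peripheral_snr_decay = 0.25))
  seg <- segment_bscan(ph$image)
  errs <- seg_mspe(seg, ph$truth)
  expect_lt(max(errs), 1.5)
  expect_named(seg$curves, c("anterior", "epithelium_stroma", "posterior"))
})

test_that("a two-interface phantom configured for two layers yields ordered curves", {
  spec <- clean_phantom_spec(interfaces = list(
    list(name = "anterior", base_depth_px = 80, curv_x = 0.0015,
         brightness = 1.0, fill_below = 0.35),
    list(name = "posterior", base_depth_px = 220, curv_x = 0.0017,
         brightness = 0.70, fill_below = 0.05)))
  ph <- make_phantom_2d(spec)
  cfg <- seg_config(layers = list(posterior = c(300, 1200)))
  seg <- segment_bscan(ph$image, cfg)
  expect_length(seg$curves, 2)
  both <- seg$curves$anterior$valid & seg$curves$posterior$valid
  expect_true(all(seg$curves$anterior$positions[both] <
                    seg$curves$posterior$positions[both]))
  expect_lt(max(seg_mspe(seg, ph$truth)), 1)
})

test_that("all curves are invalid exactly on flagged artifact columns", {
  spec <- phantom_spec(seed = 5,
                       central_artifact = list(columns = 125:129, amplitude = 0.6))
  ph <- make_phantom_2d(spec)
  seg <- segment_bscan(ph$image)
  for (cur in seg$curves) expect_false(any(cur$valid[125:129]))
  flagged <- seg$report$central_columns + seg$crop_offset[2]
  expect_identical(sort(flagged), 125:129)
})

test_that("interfaces are strictly depth-ordered at every mutually valid column", {
  ph <- make_phantom_2d(phantom_spec(seed = 9))
  seg <- segment_bscan(ph$image)
  cs <- seg$curves
  for (i in 2:length(cs)) {
    both <- cs[[i - 1]]$valid & cs[[i]]$valid
    expect_true(all(cs[[i]]$positions[both] > cs[[i - 1]]$positions[both]))
  }
})

test_that("segment_bscan is deterministic end to end", {
  ph <- make_phantom_2d(phantom_spec(seed = 4))
  a <- segment_bscan(ph$image)
  b <- segment_bscan(ph$image)
  expect_identical(a$curves, b$curves)
  expect_identical(a$shifts, b$shifts)
})

test_that("pipeline errors carry their stage label", {
  px <- matrix(0.5, 50, 20)     # constant image: no candidates anywhere
  expect_error(segment_bscan(bscan_image(px, 4, 15)), "\\[stage ")
})
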