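## Shared phantom configurations for the test suite.

## The standard noiseless study phantom: default geometry without noise
## or lateral SNR falloff.
clean_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(speckle_sigma = 0, peripheral_snr_decay = 0, seed = seed, ...)
}

## Volume phantom scaled for desk-size 3D runs (20 frames x 64 columns x
## 300 rows); mild speckle unless overridden.
volume_phantom_spec <- function(seed = 1L, speckle_sigma = 0.1,
                                peripheral_snr_decay = 0.25, n_frames = 20L,
                                perturb_amp = 1.5, ...) {
  phantom_spec(
    width = 64L, height = 300L, n_frames = n_frames,
    interfaces = list(
      list(name = "anterior", base_depth_px = 60, curv_x = 0.004,
           curv_v = 0.02, brightness = 1.0, fill_below = 0.35),
      list(name = "epithelium_stroma", base_depth_px = 78, curv_x = 0.0042,
           curv_v = 0.02, brightness = 0.85, fill_below = 0.30),
      list(name = "posterior", base_depth_px = 200, curv_x = 0.0045,
           curv_v = 0.022, brightness = 0.70, fill_below = 0.05)),
    perturb_amp = perturb_amp, perturb_period = 48,
    peripheral_thickening_px = 2,
    speckle_sigma = speckle_sigma,
    peripheral_snr_decay = peripheral_snr_decay, seed = seed, ...)
}

## A small two-band test image: one bright row at `r1`, one at `r2`,
## constant background; width >= 9 so artifact detection applies.
two_band_image <- function(r1 = 30L, r2 = 60L, height = 100L, width = 12L,
                           b1 = 0.9, b2 = 0.6, bg = 0.05,
                           axial_res_um = 10) {
  px <- matrix(bg, height, width)
  px[r1, ] <- b1
  px[r2, ] <- b2
  bscan_image(px, axial_res_um, 10)
}

## MSPE of a segmentation result against phantom truth, by interface name.
seg_mspe <- function(seg, truth) {
  vapply(names(truth), function(nm)
    mspe(seg$curves[[nm]], truth[[nm]])$mean_px, numeric(1))
}
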