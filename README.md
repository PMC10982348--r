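# octseg

Automatic segmentation of corneal layer interfaces in optical coherence
tomography (OCT) images — the air–epithelium (anterior), epithelium–stroma,
and endothelium–aqueous (posterior) boundaries — in 2D B-scans and 3D
volumes. The package is aimed at ophthalmic image-analysis work where layer
positions feed thickness maps, curvature estimates, or surface
reconstructions, and where manual delineation of hundreds of B-scans is not
an option.

## Method

Each A-scan (image column) is processed in three stages:

1. **Preprocess** — apex detection from the row-sum profile, crop to the
   corneal region of interest, exact removal of horizontal stripe
   artifacts by row-mean equalization, exclusion (not repair) of central
   saturation columns exceeding a multiple of the peripheral column mean,
   and adaptive Wiener denoising.

2. **Coarse anterior + refinement** — candidate boundary pixels are
   prominent local maxima of the A-scan; a candidate pair (y₁, y₂) is
   scored by the boundary function

   G = |I(x, y₁) − I(x, y₂)| − min_{μ∈[y₁,y₂]} I(x, μ),

   and the anterior position is the top pixel of the best pair, regularized
   by a robust second-order polynomial fit. The boundary proper is the
   maximum of the absolute forward-difference axial gradient |g| within ±5
   px of the fitted curve, propagated from the image centre outward: a
   candidate offset δ is scored by |g| at the candidate plus the
   decay-weighted |g| of all committed pixels shifted by δ, with geometric
   weights w(d) = p(1 − p)^d. A first-order, 21-point Savitzky–Golay filter
   smooths the result.

3. **Deeper layers** — each deeper interface starts as the refined anterior
   profile shifted by argmax_{μ∈S} Σₓ |g(x, f(x) + μ)| over a
   thickness-derived window S, then refined with a centre-to-periphery
   linear-growth decay profile (low p centre, high p periphery) plus a
   constant-low-p smoothing pass and a running median.

In 3D the same machinery runs over volumes: pooled coarse candidates feed a
robust quadratic surface fit, refinement visits lateral positions in
city-block geodesic order from the corneal centre, deeper surfaces come
from the volumetric shift search, and height maps are median-smoothed.

Accuracy is measured as the mean unsigned surface positioning error (MSPE):
the mean |segmented − reference| axial distance in pixels (and µm) over the
mutually valid columns.

A synthetic phantom generator (`make_phantom_2d()`, `make_phantom_3d()`)
renders B-scans and volumes with known interface geometry, speckle,
peripheral SNR falloff and injectable artifacts, so the full pipeline is
testable without clinical data. See the vignette
(`vignettes/corneal-segmentation.Rmd`) for the model, parameter rationale
and known limitations.

## Worked example

```r
library(octseg)

## a 256 x 400 px phantom with speckle and peripheral SNR falloff
ph  <- make_phantom_2d(phantom_spec(seed = 1))
seg <- segment_bscan(ph$image)
seg
#> <corneal_seg> 400 x 256 B-scan, apex row 79, 3 interface(s)
#>   anterior            220 valid columns, axial range [79, 100]
#>   epithelium_stroma   220 valid columns, axial range [97, 120]
#>   posterior           220 valid columns, axial range [219, 246]
#>   layer shifts (px): epithelium_stroma = 18, posterior = 140

mspe(seg$curves$posterior, ph$truth$posterior, axial_res_um = 4)
#> MSPE: 0.091 +/- 0.288 px (0.364 um) over 220 positions
```

The printed summary says the apex was found at row 79, the three interfaces
were segmented on the 220 columns that survive the lateral crop, and the
epithelium–stroma and posterior interfaces were located 18 px (72 µm) and
140 px (560 µm) below the anterior surface — consistent with corneal
anatomy at 4 µm axial sampling. The posterior boundary lands within 0.09 px
(0.36 µm) of the generator's ground truth on average.

`plot(seg, image = ph$image)` overlays the curves on the B-scan;
`as.data.frame(seg)` and `write_boundary_csv(seg, "out.csv")` export them.
Volumes go through `segment_volume()` and `write_surface_csv()`.

A thin command-line wrapper ships in `inst/cli/octseg.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","octseg.R",package="octseg"))')" \
    segment2d --out results/ scan1.tiff scan2.tiff
```

with subcommands `segment2d`, `segment3d`, `phantom`, and `evaluate`; every
run writes a manifest with the configuration snapshot and content hashes of
all outputs.

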