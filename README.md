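# ctpangio

Derives cerebral arteriograms (CTA) and venograms (CTV) from 4D CT-perfusion
(CTP) series, and renders individual vessels-of-interest as centerlines and
straightened (curved-planar-reformatted) volumes.

Clinical single-phase CTA/CTV images are timed snapshots: they truncate
late-filling veins and mix arterial and venous voxels. A CTP acquisition
already contains the whole bolus passage — every voxel carries a
time-attenuation curve (TAC), its Hounsfield value over time — so both
vascular systems can be computed from one dataset. The package is aimed at
researchers working on stroke imaging pipelines who need reproducible,
scriptable CTA/CTV derivation and vessel geometry processing, validated
without patient data.

## Method at a glance

1. **Skull stripping** — voxels ≥ 155 HU in the pre-contrast first frame
   form the skull mask; everything outside the largest enclosed cavity is
   removed (set to −1024 HU) in all frames.
2. **Vessel segmentation** — each TAC is convolved with a digitized
   first-order derivative-of-Gaussian kernel (σ = 3 frames, 1 × 5 taps) and
   the absolute responses are summed, FG = Σᵢ |v′ᵢ|. FG is zero for
   constant TACs and large for vessels; thresholding FG (Otsu on
   log(FG+1) by default) gives the vessel mask.
3. **Artery–vein separation** — per-voxel time-to-peak (TTP) from the
   linear interpolation of the derivative's zero crossing,
   a = (v′₍I+1₎−v′₍I₎)/(t₍I+1₎−t₍I₎), b = v′₍I+1₎ − a·t₍I+1₎,
   t_ttp = −b/a. The TTP histogram is bimodal (contrast reaches arteries
   first); the valley between its two peaks, V_ttp, splits the vessel mask
   into CTA (TTP ≤ V_ttp) and CTV.
4. **Centerline extraction** — the vessel-of-interest mask is meshed
   (marching tetrahedra at the 0.5 isosurface), sliced by marching normal
   planes, each closed contour contributes a robustly fitted cross-section
   centre, and Dijkstra's shortest path between the snapped seed points
   through those centres is the centerline a₁…aₙ with difference-scheme
   tangents n→ᵢ.
5. **Straightening** — a square sampling plane is propagated along the
   centerline by the Rodrigues rotation
   v′ = cos θ·v + (1−cos θ)(u·v)u + sin θ(u×v) between consecutive
   tangents (a discrete rotation-minimizing frame), the image is
   trilinearly resampled on each plane, and the planes are stacked along a
   new z-axis. Per-slice lumen areas localize stenoses and dilations.

Synthetic phantom generators (`phantom_scene()`, `make_deviation_phantom()`,
`make_stenosis_phantom()`) provide gamma-variate bolus dynamics, curved
tubes with side branches, and stenosis/dilation tubes with analytic ground
truth, so the whole pipeline is testable offline. See the vignette
(`vignettes/ctp-angiography.Rmd`) for the full model description and design
rationale.

## Worked example

```r
library(ctpangio)

# a synthetic CTP head: skull shell, enhancing tissue, one artery (TTP 10 s),
# one vein (TTP 20 s), 2 HU noise
scene   <- phantom_scene(noise_sigma = 2, seed = 3)
phantom <- rasterize_scene(scene)

run <- run_pipeline(phantom$series)
#> no vessel-of-interest mask supplied; stopping after artery/vein separation
run
#> <pipeline_run> stages: strip -> vesselseg -> avsep
#>   FG threshold 64.17, v_ttp 10.91 s
#>   artery 647 voxels, vein 874 voxels
```

The run manifest records the automatically chosen FG threshold (64.17) and
the TTP-histogram valley (10.91 s, between the 10 s arterial and 20 s venous
modes). Against the phantom's labels this run segments the vessels with
Dice 1.0 and classifies every segmented vessel voxel correctly
(artery/vein accuracy 1.0).

Extracting and straightening the artery as the vessel-of-interest:

```r
voi <- phantom$labels == 1
attributes(voi) <- attributes(phantom$labels)
ref <- phantom$centerlines[[1]]        # analytic axis, used here as seeds

cl <- extract_centerline(voi, ref[1, ], ref[nrow(ref), ], step = 1)
centerline_deviation(cl, ref)
#> <deviation_summary> mean 0.053 +/- 0.023 mm, max 0.084 mm (n = 4 points)

stack <- propagate_planes(cl, half_size_mm = 4, in_plane_spacing = 0.5, step = 0.5)
sv    <- resample_on_planes(voi, stack, sentinel = 0)
assess_caliber_profile(sv)
#> <caliber_profile> 28 slices, median area 4.88 mm^2
#>   min area at s = 5 mm, max area at s = 0 mm
#>   0 stenotic and 0 dilated interval(s) flagged
```

The extracted centerline deviates from the analytic axis by ~0.05 mm on
average, and the straightened constant-radius tube shows a flat caliber
profile (median 4.88 mm² ≈ π·1.2², the tube's lumen) with no stenosis or
dilation flagged — as it should for an unablated vessel. `tidy()`,
`glance()` and `autoplot()` methods turn each result into tibbles and
ggplots; a thin command-line wrapper lives at `inst/cli/ctpangio`.

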