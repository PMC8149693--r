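# aosim

Adaptive-optics three-dimensional structured-illumination microscopy
(AO-3DSIM) in R: simulation, reconstruction, and both flavours of
wavefront correction, validated end to end on synthetic phantoms.

3D-SIM illuminates the sample with a three-beam interference pattern
(3 orientations × 5 phases per plane, 15 raw frames) and reassembles the
frequency-shifted object components `D̃_{j,m}(k)` into a super-resolved
spectrum with a generalized Wiener filter

```
S̃(k) = Σ_{j,m} a*_{j,m} {H̃_m(k+mp_j)[1−G(k+mp_j)]}* D̃_{j,m}(k+mp_j)
        ───────────────────────────────────────────────────────────── · A(k)
        Σ_{j,m} |a_{j,m}|² |H̃_m(k+mp_j)[1−G(k+mp_j)]|²  +  w²
```

where `H̃_m` are the per-order transfer functions (the first order being
two axially shifted copies of the zeroth), `G` a 9-pixel top-hat notch,
`A` a triangle apodization with cutoffs `4·NA/λ` and `NA²/λ`, and the
complex weights `a_{j,m}` and wave vectors `p_j` are estimated from the
data by maximizing the OTF-overlap correlation. Deep-tissue aberrations —
expanded in Noll-indexed Zernike modes — collapse exactly this overlap
signal, which is why the package also implements both corrections used in
AO microscopy:

* **sensorless modal AO** — trial Zernike modes, a spatial-frequency
  image-quality metric `M = Σ|Ĩ|(1−g_h)·circ / Σ|Ĩ|g_l·circ`, and a
  quadratic fit per mode (25 acquisitions per 5-mode iteration), with a
  confocal guide-star peak metric as the robust variant;
* **direct wavefront sensing** — a Shack–Hartmann simulator (146 µm
  lenslets, f = 5.2 mm, dynamic range d²/2f = 2.05 µm), cross-correlation
  spot tracking, Fourier-domain slope integration, Gram–Schmidt Zernike
  decomposition, and closed-loop control of a 69-actuator deformable
  mirror model.

Everything runs on synthetic data from the built-in forward simulator
(bead/filament/shell phantoms, aberrated PSFs, Poisson + read noise,
seeded and bit-reproducible), so every algorithm is testable on a laptop.

## Worked example

Simulate a 50 nm bead, acquire a raw SIM stack on a 128×128×16 grid
(89 nm pixels, 200 nm steps, red channel: 670 nm emission, NA 1.2), and
reconstruct:

```r
library(aosim)

cfg     <- optical_config(grid_xy = 128, n_z = 16)
phantom <- make_phantom("beads", cfg, n = 1, diameter_nm = 50,
                        seed = 3, margin_frac = 0.45)
stack   <- simulate_sim_stack(phantom, zernike_coeffs(), si_pattern(), cfg)
res     <- sim_reconstruct(stack)

glance(res$estimate)
#> # A tibble: 3 × 6
#>   orientation       p_x      p_y   p_mag    phase_rad failed
#>         <int>     <dbl>    <dbl>   <dbl>        <dbl> <lgl>
#> 1           1  0.00146   0       0.00146  0.000000126 FALSE
#> 2           2 -0.000732  0.00127 0.00146 -0.0000477   FALSE
#> 3           3 -0.000732 -0.00127 0.00146  0.0000477   FALSE

wf <- simulate_widefield(phantom, zernike_coeffs(), cfg)
volume_fwhm(wf, cfg$pixel_xy, cfg$z_step, "x")                       # 277 nm
volume_fwhm(res$recon$volume, res$recon$pixel_xy, res$recon$z_step, "x")  # 165 nm
volume_fwhm(wf, cfg$pixel_xy, cfg$z_step, "z")                       # 789 nm
volume_fwhm(res$recon$volume, res$recon$pixel_xy, res$recon$z_step, "z")  # 633 nm
```

The estimated wave-vector magnitude 0.00146 cycles/nm is the pattern
fundamental (1/683.34 nm); the bead's lateral width drops from 277 nm
(diffraction limit, ≈ λ/2NA) to 165 nm and the axial width from 789 to
633 nm — the lateral gain ≈ 1.7–1.8 matches the theoretical enhancement
`resolution_enhancement(670, 1.2, 341.67) = 1.817` (the period argument
is the finest-fringe spacing, half the fundamental). On a point-source
phantom the wave-vector search is degenerate (flat correlation surface),
so the estimator warns and uses the nominal frequency — the standard
preset-frequency protocol for such simulations.

Sensorless correction of an injected aberration:

```r
inject <- zernike_coeffs(c(`5` = 0.15))            # 0.15 µm astigmatism
imager <- function(cf) {
  tot <- coeffs_from_dense(coeffs_dense(cf, 15) + coeffs_dense(inject, 15))
  simulate_widefield(phantom, tot, cfg)[, , 9]
}
mcfg <- metric_config(cfg)
loop <- modal_correction_loop(imager, trial_schedule(n_iterations = 2),
                              function(im) image_quality_metric(im, mcfg))
loop$coeffs   # ≈ −0.15 µm on Noll 5: the injected aberration, cancelled
```

A command-line wrapper ships in `inst/scripts/ao3dsim` with verbs
`simulate`, `reconstruct`, `ao-sensorless`, `ao-shwfs`, `evaluate` and
`sweep`; raw stacks and volumes are exchanged as multi-page 32-bit TIFF
with YAML sidecars.

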