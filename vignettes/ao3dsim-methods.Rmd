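---
title: "Adaptive-optics 3D-SIM: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-optics 3D-SIM: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(aosim)
```

Three-dimensional structured illumination microscopy (3D-SIM) doubles
lateral and improves axial resolution by illuminating the sample with a
three-beam interference pattern, acquiring phase-stepped images, and
computationally reassembling the frequency-shifted object information.
Deep in tissue the method degrades quickly: sample-induced wavefront
aberrations shrink the optical transfer function (OTF), which both lowers
image quality and starves the reconstruction of the OTF-overlap signal it
needs to locate the pattern. This package implements the complete
computational chain of an adaptive-optics (AO) 3D-SIM instrument — image
formation under pupil aberrations, the generalized-Wiener reconstruction,
sensorless modal AO, and Shack–Hartmann (SH) direct wavefront sensing with
closed-loop deformable-mirror (DM) control — entirely on synthetic
phantoms, so that every algorithm can be validated without hardware.

## Optical model

**Wavefronts.** Aberrations are modal: a wavefront is
$W(\rho,\theta)=\sum_j c_j Z_j(\rho,\theta)$ over the pupil disk, with
$Z_j$ the Noll-indexed, Noll-normalized Zernike polynomials (unit RMS, so
a coefficient in µm is directly an RMS optical-path contribution). Both
1-based Noll indexing and a 0-based relabelling (`paper_0based`, mode
$k$ = Noll $k+1$) are supported; with the latter, modes 4, 5, 6, 7 and 10
are the two astigmatisms, the two comas and primary spherical — the set
the sensorless loop corrects by default (Noll 5, 6, 7, 8, 11).
Coefficients are Noll-normalized modal amplitudes, not peak-to-valley
contributions; where an experiment is parameterized by peak-to-valley
(PV), the helper used by `aberration_sweep()` rescales a mode so max−min
over the pupil equals the requested PV.

**PSF/OTF.** Image formation is scalar Fourier optics: the amplitude PSF
at defocus $z$ is the inverse transform of
$P(\mathbf{k})\,e^{2\pi i W(\mathbf{k})/\lambda}\,e^{2\pi i k_z(\mathbf{k}) z}$
with a hard circular pupil of radius $\mathrm{NA}/\lambda$ and defocus
propagator $k_z=\sqrt{(n/\lambda)^2-|\mathbf{k}_{xy}|^2}$ ($n = 1.33$,
water immersion; NA 1.2). No vectorial high-NA or index-mismatch
corrections are applied. The intensity PSF is normalized by its
aberration-independent Parseval energy, so pure-phase aberrations conserve
total signal exactly — a property the tests rely on. The zeroth-order OTF
is the 3-D transform of the PSF; the first-order OTF of three-beam SIM is
built exactly as the transform of
$\mathrm{PSF}\cdot 2\cos(2\pi k_{za} z)$, i.e. two copies of the zeroth
order shifted axially by $\pm k_{za}$; the second order reuses the zeroth
at twice the lateral offset.

**Illumination.** The pattern is three-plane-wave interference: a mean
term, a first lateral harmonic at $1/p$ that is axially modulated at
$k_{za}=(n/\lambda_{ex})(1-\cos\theta)$ with
$\theta=\arcsin(\lambda_{ex}/(n\,p))$, and a second lateral harmonic at
$2/p$. `period_nm` ($p$) is the *fundamental* (0 vs ±1 beat) period. Pattern
periods are conventionally quoted as the finest fringe spacing, which is
half the fundamental: the red channel's 341.67 nm finest fringe
corresponds to `period_nm = 683.34` (default), the green channel's
273.33 nm to 546.67 nm. Note the finest-fringe number cannot itself be the
fundamental: a beam's lateral frequency is bounded by $n/\lambda$, and
$1/341.67\,\mathrm{nm}^{-1}$ exceeds that bound at 647 nm excitation. With
this reading the lateral support extends to
$2/p + 2\mathrm{NA}/\lambda_{em}$, which reproduces the quoted
enhancement factor $1+[\lambda/(2\,\mathrm{NA})]/341.67 = 1.82$ exactly.
The grating is biased so each ±1 beam carries about 3× the 0-beam
intensity (`order_intensity_ratio = 3`), strengthening the second
harmonic; the resulting modulation weights, normalized to a unit mean
term, are $w_1 = 2\sqrt{r}/(1+2r)$ and $w_2 = r/(1+2r)$.

Excitation-side aberrations do not weaken a coherent interference pattern;
they shift its phase and (weakly) its frequency. The simulator therefore
applies excitation aberrations only as a documented pattern-phase offset
(`phase_offset_rad`) on the ±1 orders, while emission-side aberrations act
through the detection PSF.

## Forward simulator

`make_phantom()` builds bead fields (100/200 nm spheres, anti-aliased by
5×5×5 subsampling so voxelized mass matches the analytic sphere volume),
Gaussian-tube filaments, and spherical shells (exactly empty inside the
inner radius); all randomness derives from one seed and every output is
bit-reproducible. `simulate_widefield()` convolves density with the
aberrated PSF; `simulate_sim_stack()` produces the 15 raw frames per plane
(3 orientations × 5 phases at 0, 2π/5, …, 8π/5). z-stepping moves the
object relative to the focal plane with the pattern locked to focus, which
is what couples the axial pattern modulation into the first-order OTF; in
order space each frame is
$\sum_m e^{im\varphi} (D\,e^{2\pi i m \mathbf{p}\cdot\mathbf{r}})
\ast K_m$ with $K_0=\mathrm{PSF}$,
$K_1=\mathrm{PSF}\cos(2\pi k_{za}z)$, $K_2=\mathrm{PSF}$. Convolutions
are circular (FFT); phantoms keep a dark margin so wrap-around is
negligible. Noise is Poisson shot noise on
`photons_per_unit * density + background` plus Gaussian read noise; EMCCD
excess noise is not modelled. Defaults (256×256×17 at 89 nm/200 nm) are
chosen for test speed; tests and examples in this package run at 64–128
pixels laterally, which keeps the full suite under a minute while leaving
every band relationship intact.

The SH simulator displaces each lenslet's focal spot by $f_{ML}$ times the
mean wavefront gradient over the lenslet footprint (146 µm pitch, 5.2 mm
focal length, ~14 lenslets across a 2.27 mm conjugated pupil) and renders
diffraction-scale Gaussian spots; gradients beyond the
$d^2/(2f_{ML}) = 2.05$ µm dynamic range mark the lenslet saturated and
produce no spot.

## 3D-SIM reconstruction

`separate_orders()` inverts the 5×5 phase-mixing matrix
$M_{\varphi m}=e^{im\varphi}$ per orientation (exactly, the matrix being
unitary up to scale for equally spaced phases; a warned pseudo-inverse
otherwise) after applying a real-space 3-D Tukey window (γ = 0.08) that
suppresses FFT edge discontinuities — the window appears in the
reconstruction formula as a spectral convolution; applying it in real
space before the transform is the same operation, and it commutes with
the per-pixel separation.

`estimate_pattern_params()` finds, per orientation, the pattern wave
vector by maximizing the normalized overlap correlation between the
zeroth-order component and the back-shifted second-order component
(purely lateral, twice the wave vector — the tightest constraint), using
a coarse ±2-pixel scan followed by Nelder–Mead sub-pixel refinement with
spatial-ramp (exact, non-integer) shifts. The search objective is
evaluated on the $k_z=0$ plane, where z-sums make each trial two small
2-D FFTs; final weights use the full 3-D statistic. The least-squares
amplitude ratio at the optimum is the complex weight $a_{j,m}$
($a_{j,0}=1$): its magnitude is the OTF overlap amplitude, and
$\arg a_{j,1}$ the global pattern phase. Noise-free recovery is ~10⁻⁵
relative in $|p|$ and ~10⁻⁴ rad in phase. Two numerical points deserve
note. First, shifting a *centered* kernel by a non-integer frequency
requires the spatial ramp to use signed coordinates about the centre
pixel — using unsigned indices mis-phases the wrapped half and destroys
off-grid correlations. Second, a featureless object spectrum (a single
point source) makes the wave vector unidentifiable: the shift changes only
a global phase, so the correlation magnitude is flat. The estimator
detects a flat search surface and falls back, with a warning, to the
nominal wave vector — the preset-frequency protocol that is also standard
for point-like simulation phantoms.

`wiener_reconstruct()` assembles
$$\tilde S(\mathbf{k}) = \frac{\sum_{j,m} a_{j,m}^{*}
\{\tilde H_m(\mathbf{k}+m\mathbf{p}_j)[1-G(\mathbf{k}+m\mathbf{p}_j)]\}^{*}
\tilde D_{j,m}(\mathbf{k}+m\mathbf{p}_j)}
{\sum_{j,m} |a_{j,m}|^2 |\tilde H_m(\mathbf{k}+m\mathbf{p}_j)
[1-G(\mathbf{k}+m\mathbf{p}_j)]|^2 + w^2}\; A(\mathbf{k})$$
on an output grid upsampled 2× laterally (raw components are
Fourier-embedded before shifting). The weights enter as a matched filter
(conjugated) in the numerator *and* as $|a|^2$ in the denominator; with
weights normalized near unity this reduces to the unweighted-denominator
form, but under this package's physical convention
($|a_1|\approx0.12$, $|a_2|\approx0.21$ at beam ratio 3) the $|a|^2$
weighting is required for each band to contribute a flat unit response —
without it the side bands are suppressed by $|a|^2$ and the
reconstruction is *broader* than widefield.

Filters: $G$ is a top-hat notch of 9-pixel diameter on a 1024-wide grid
(physical radius grid-independent), applied as a lateral cylinder at each
shifted band origin — removing the $k_z$ line at each carrier is what
suppresses residual stripes and restores optical sectioning. $A$ is the
modified triangle
$[(1-a_{xy}k_{xy}/k^{xy}_{cut})(1-a_z|k_z|/k^{z}_{cut})]^n$, clipped at
zero, with $k^{xy}_{cut}=4\mathrm{NA}/\lambda$ and
$k^{z}_{cut}=\mathrm{NA}^2/\lambda$; $a_{xy},a_z\in[0.5,1]$,
$n\in[0.5,2]$ are exposed for empirical tuning, defaults 1, 1, 1. The
Wiener constant is relative: $w^2 = 10^{-4}\times\max(\text{denominator})$
by default. A $10^{-3}$ fraction — natural for an unweighted
denominator — over-regularizes the $|a|^2$-weighted one, whose peak is
set by the unit-weight zeroth order while side bands carry only
$|a|^2\sim0.02$–0.05; at $10^{-4}$ a noise-free bead reconstructs with a
lateral gain of ~1.8 over widefield, matching the theoretical support
ratio, and the axial width shrinks as the first-order side bands fill the
missing cone. Components whose estimated weight magnitude falls below
`min_overlap` are dropped from both sums; dropping all side orders
reduces the pipeline exactly to a Wiener-deconvolved widefield image, a
regression anchor in the tests.

## Sensorless adaptive optics

The image-quality metric is the high/low spatial-frequency ratio
$$M=\frac{\sum |\tilde I|(1-g_h)\,\mathrm{circ}}
        {\sum |\tilde I|\,g_l\,\mathrm{circ}},$$
with Gaussian weights and a mask at the widefield cutoff
$2\mathrm{NA}/\lambda$. It depends only on the spectral modulus, hence is
translation-invariant, and vanishes for structureless images. Defaults
place the $g_h$ FWHM at $\mathrm{NA}/(2\lambda)$ — so the numerator
emphasizes frequencies above that — and the $g_l$ FWHM a fifth of it;
both are tunable because the metric's sensitivity depends on the sample's
spectrum (point-like objects are ideal; spectrally concentrated or noisy
images can defeat it, which is why a confocal guide-star spot with the
simple 3×3-smoothed peak metric is offered as the robust alternative).

`modal_correction_loop()` acquires 3 or 5 trial images per mode at
strengths $(-a,0,a)$ or $(-2a,-a,0,a,2a)$ (default step 0.2 µm; 0.4 µm
suits large aberrations), fits a parabola, and takes its vertex as the
correction — 25 acquisitions per 5-mode iteration. Modes are evaluated
independently from the iteration's starting state and combined linearly
(sequential accumulation is available). A nonnegative fitted curvature
flags the mode as not corrected (vertex 0); vertices beyond the trial
range are clipped to it and flagged. Iterations repeat with the step
halved, stopping early when a check image shows no improvement. On
noise-free bead phantoms, two iterations recover a 0.15 µm injected
astigmatism to better than 0.02 µm. Correcting on an ROI simply evaluates
the metric there, trading field-average quality for local quality.

## Shack–Hartmann sensing and closed loop

Spot displacements are measured by per-lenslet FFT cross-correlation
against the aberration-free reference frame with Gaussian (log-parabolic)
3×3 peak interpolation — exact for Gaussian spots, avoiding the
pixel-locking bias of a plain parabola. Slopes are
displacement/$f_{ML}$; undetectable spots invalidate their lenslet.

`ft_reconstruct_wavefront()` integrates the slope fields spectrally,
$\tilde W = (-ik_x\tilde S_x - ik_y\tilde S_y)/(2\pi|k|^2)$ with the DC
term zeroed. Three measures control the bias of this estimator on a
14×14 masked grid: the slope fields are spline-upsampled 4× first (the
trigonometric interpolant of so few samples otherwise inflates
fourth-order radial modes); the grids are mirror-extended with even
symmetry (no periodic-boundary bias); and a few fixed-point iterations
add back the integral of the in-pupil slope residual, making the
surface's spectral gradient match the measurement. A leading-order
Taylor correction $s - (d^2/24)\nabla^2 s$ undoes the lenslet-footprint
box averaging. The Noll 5–15 coefficient round trip through
sense–reconstruct–decompose is then accurate to ≤ 5% at 0.2 µm
amplitude. A known limitation: the map-level RMS residual for the
radial-order-4 family (Noll 11–13) remains 6–9%, an irreducible
defocus-like leakage of box-averaged $r^4$ slopes at this lenslet count;
it is harmless downstream because defocus is removed before correction.

`decompose_to_zernike()` projects onto pixelated Zernike modes
orthogonalized by Gram–Schmidt (QR), reporting coefficients in the
original basis through the mixing matrix — algebraically a least-squares
fit on the mask, which the tests verify against explicit normal
equations; the naive non-orthogonal projection is kept as a comparison
method and demonstrably leaks more crosstalk on coarse grids. Piston,
tip, tilt and defocus are always removed before correction: tip/tilt
largely reflects registration between measured and reference spot
patterns, and defocus is biased by out-of-focus light.

The DM model has 69 actuators (9×9 lattice minus corners) across the
pupil with Gaussian influence functions at 30% inter-actuator coupling;
command fitting is least squares on the pupil mask and is a projection
(refitting a rendered surface returns identical commands).
`closed_loop_correct()` iterates measure → remove piston/tip/tilt/defocus
→ fit → apply with gain (default 0.5, a conventional stable choice),
recording residual RMS and aborting if it grows three iterations running.
An injected 0.4 µm astigmatism + 0.3 µm spherical converges to ~1.5% of
the initial residual in 10 iterations.

## Evaluation metrics

`snr()` follows the adaptive-threshold recipe: object pixels exceed the
Gaussian-weighted local mean (σ = block/6, block 51 px) — plus a guard of
5 standard deviations of the below-threshold set, without which half of
any noise field sits above its own local mean and dilutes the object —
and SNR is mean(object)/sd(background); a pure-noise ROI raises an error
rather than returning a number. `fwhm()` is a four-parameter Gaussian
least-squares fit (Levenberg–Marquardt), FWHM $=2\sqrt{2\ln 2}\,\sigma$,
offset-invariant and exact on noiseless Gaussians.

`aberration_sweep()` reruns the aberration experiment end to end: bead
stacks under single-mode aberrations scaled to PV ∈ {0.2, 0.4, 0.6} µm,
order separation, and overlap weights at the *preset* pattern frequency
and phase, normalized per orientation/order to the flat-wavefront
baseline. Over this range the second-order overlap amplitude decays
monotonically for astigmatism, coma and spherical at every orientation,
and for astigmatism it depends strongly on pattern orientation (the
aberration is anisotropic). Two measured limitations shaped the default
range: beyond ~0.7 µm PV the aberrated OTF's ringing re-aligns with the
ideal kernel and the overlap amplitude stops being monotone; and the
first-order (axial side-band) amplitude for spherical crosses near zero
around 0.4 µm PV. The sweep reproduces trends, not the bar heights of any
specific instrument, whose bead fields and amplitude grids are not
published.

## What the synthetic data do and do not show

The generator reproduces the features the algorithms depend on: correct
band structure and modulation weights, aberration-dependent OTF overlap,
Poisson-plus-read noise, lenslet-geometry spot displacement with
saturation. It does not model scattering, depth-dependent (anisoplanatic)
aberrations, refractive-index mismatch, photobleaching, or EMCCD excess
noise. Green tests therefore demonstrate algorithmic correctness and the
stated trends, not performance on any particular biological sample; real
tissue adds exactly the anisoplanatism and scattering that motivate ROI
correction and guide-star sensing in practice.

## Worked example

```{r example, eval = FALSE}
cfg <- optical_config(grid_xy = 128, n_z = 16)
phantom <- make_phantom("beads", cfg, n = 1, diameter_nm = 50,
                        seed = 3, margin_frac = 0.45)
stack <- simulate_sim_stack(phantom, zernike_coeffs(), si_pattern(), cfg)
res <- sim_reconstruct(stack)     # separation + estimation + Wiener assembly
glance(res$estimate)              # wave vectors, phases, failure flags
wf <- simulate_widefield(phantom, zernike_coeffs(), cfg)
volume_fwhm(wf, cfg$pixel_xy, cfg$z_step, "x")            # ~277 nm
volume_fwhm(res$recon$volume, res$recon$pixel_xy,
            res$recon$z_step, "x")                        # ~165 nm
```
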