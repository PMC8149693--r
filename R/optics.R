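#' Optical configuration
#'
#' Single source of truth for wavelengths, numerical aperture, immersion
#' index, sampling and grid sizes. All frequency-space scaling derives from
#' these values.
#'
#' Defaults correspond to the red imaging channel of a water-immersion
#' 1.2 NA system: 647 nm excitation, 670 nm emission, 89 nm camera pixel at
#' the sample, 200 nm z-step.
#'
#' @param wavelength_em Emission wavelength, nm.
#' @param wavelength_ex Excitation wavelength, nm.
#' @param na Numerical aperture (< `n_immersion`).
#' @param n_immersion Immersion refractive index.
#' @param pixel_xy Lateral pixel size, nm. Must satisfy the SIM Nyquist
#'   condition `pixel_xy <= wavelength_em / (4 * na)` so that the widefield
#'   band fits the raw grid.
#' @param z_step Axial step, nm.
#' @param grid_xy Lateral grid size (pixels).
#' @param n_z Number of z planes.
#' @return An `optical_config` object.
#' @export
optical_config <- function(wavelength_em = 670, wavelength_ex = 647,
                           na = 1.2, n_immersion = 1.33,
                           pixel_xy = 89, z_step = 200,
                           grid_xy = 256, n_z = 17) {
  vals <- c(wavelength_em, wavelength_ex, na, n_immersion, pixel_xy, z_step, grid_xy, n_z)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all optical parameters must be positive and finite", call. = FALSE)
  }
  if (na >= n_immersion) stop("`na` must be smaller than `n_immersion`", call. = FALSE)
  if (pixel_xy > wavelength_em / (4 * na) * 2) {
    # raw-data Nyquist: widefield cutoff 2 NA / lambda must be below 1/(2 px)
    stop(sprintf("pixel_xy = %g nm undersamples the widefield band (max %.1f nm)",
                 pixel_xy, wavelength_em / (2 * na)), call. = FALSE)
  }
  structure(list(wavelength_em = wavelength_em, wavelength_ex = wavelength_ex,
                 na = na, n_immersion = n_immersion,
                 pixel_xy = pixel_xy, z_step = z_step,
                 grid_xy = as.integer(grid_xy), n_z = as.integer(n_z)),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(paste0("<optical_config> em %g nm / ex %g nm, NA %g (n = %g)\n",
                     "  grid %d x %d x %d, pixel %g nm, z-step %g nm\n"),
              x$wavelength_em, x$wavelength_ex, x$na, x$n_immersion,
              x$grid_xy, x$grid_xy, x$n_z, x$pixel_xy, x$z_step))
  invisible(x)
}

# Lateral frequency grids (cycles/nm) in unshifted FFT layout.
kgrid_xy <- function(n, pixel) {
  k <- fft_freq(n, pixel)
  kx <- matrix(k, n, n, byrow = TRUE)
  ky <- matrix(k, n, n)
  list(kx = kx, ky = ky, kr = sqrt(kx^2 + ky^2))
}

# Centered z coordinates (nm) for n planes.
z_coords <- function(n_z, z_step) (seq_len(n_z) - (floor(n_z / 2) + 1)) * z_step

# Complex pupil function P * exp(2 pi i W / lambda) on the unshifted k grid,
# plus the defocus propagator kz (cycles/nm). `wavelength` selects the
# emission or excitation pupil scaling.
pupil_field <- function(coeffs, config, wavelength = config$wavelength_em,
                        grid_xy = config$grid_xy) {
  kg <- kgrid_xy(grid_xy, config$pixel_xy)
  k_pupil <- config$na / wavelength
  k_nyq <- 1 / (2 * config$pixel_xy)
  if (k_pupil >= k_nyq) {
    stop("pupil radius reaches the grid Nyquist frequency: increase grid sampling",
         call. = FALSE)
  }
  mask <- kg$kr <= k_pupil
  w_um <- matrix(0, grid_xy, grid_xy)
  if (!inherits(coeffs, "zernike_coeffs")) coeffs <- zernike_coeffs(coeffs)
  idx <- attr(coeffs, "indices")
  if (length(idx)) {
    rho <- kg$kr / k_pupil
    theta <- atan2(kg$ky, kg$kx)
    for (i in seq_along(idx)) {
      w_um <- w_um + as.numeric(coeffs)[i] * zernike_eval(idx[i], rho, theta)
    }
  }
  lambda_um <- wavelength / 1000
  field <- mask * exp(2i * pi * w_um / lambda_um)
  kz <- sqrt(pmax((config$n_immersion / wavelength)^2 - kg$kr^2, 0))
  list(field = field, mask = mask, kz = kz, k_pupil = k_pupil, kg = kg)
}

#' Aberrated 3-D point-spread function
#'
#' Scalar Fourier-optics model: each z slice is
#' `|IFT{ P(k) exp(2 pi i W(k)/lambda) exp(2 pi i k_z(k) z) }|^2` with the
#' defocus propagator `k_z = sqrt((n/lambda)^2 - |k_xy|^2)`. The volume is
#' normalized to unit sum using the aberration-independent Parseval energy,
#' so a pure-phase aberration conserves total energy exactly.
#'
#' @param coeffs Aberration as [zernike_coeffs] (um, Noll-normalized modes).
#' @param config An [optical_config].
#' @param n_z,z_step Optional overrides of the config axial sampling.
#' @param wavelength Pupil wavelength, nm (default: emission).
#' @return A `psf3d` object: real array `(y, x, z)` in centered layout plus
#'   sampling metadata.
#' @export
compute_psf3d <- function(coeffs = zernike_coeffs(), config = optical_config(),
                          n_z = config$n_z, z_step = config$z_step,
                          wavelength = config$wavelength_em) {
  pf <- pupil_field(coeffs, config, wavelength)
  n <- config$grid_xy
  zs <- z_coords(n_z, z_step)
  vol <- array(0, c(n, n, n_z))
  for (iz in seq_along(zs)) {
    a <- ifft(pf$field * exp(2i * pi * pf$kz * zs[iz]))
    vol[, , iz] <- fftshift(Mod(a)^2)
  }
  # Parseval: per-slice energy = sum(|P|^2)/n^2, independent of phase and z.
  vol <- vol / (sum(pf$mask) / n^2 * n_z)
  structure(list(volume = vol, pixel_xy = config$pixel_xy, z_step = z_step,
                 n_z = as.integer(n_z), wavelength = wavelength,
                 config = config),
            class = "psf3d")
}

#' @export
print.psf3d <- function(x, ...) {
  cat(sprintf("<psf3d> %d x %d x %d, pixel %g nm, z-step %g nm, lambda %g nm\n",
              dim(x$volume)[1], dim(x$volume)[2], x$n_z, x$pixel_xy, x$z_step,
              x$wavelength))
  invisible(x)
}

#' Optical transfer function of a given diffraction order
#'
#' For `order = 0` this is the 3-D Fourier transform of the PSF (DC
#' normalized to 1 for a unit-sum PSF). The first-order transfer function of
#' three-beam structured illumination consists of two copies of the zeroth
#' order shifted axially by the +/- axial pattern frequency; it is computed
#' exactly as the transform of `psf * 2 cos(2 pi k_z_axial z)`. The
#' second-order transfer function is an unshifted copy of the zeroth order
#' (its lateral displacement by `2 p` is applied where it is used).
#'
#' @param psf A [compute_psf3d] result.
#' @param order Integer order m in `{-2, -1, 0, 1, 2}`.
#' @param axial_freq_nm Axial pattern frequency (cycles/nm); required for
#'   `|order| == 1` (see [si_axial_frequency]).
#' @return An `otf3d` object: complex array in unshifted FFT layout.
#' @export
compute_otf3d <- function(psf, order = 0, axial_freq_nm = NULL) {
  stopifnot(inherits(psf, "psf3d"))
  if (!order %in% -2:2) stop("unknown order: must be one of -2..2", call. = FALSE)
  vol <- psf$volume
  if (abs(order) == 1) {
    if (is.null(axial_freq_nm)) {
      stop("`axial_freq_nm` is required for first-order transfer functions", call. = FALSE)
    }
    zs <- z_coords(psf$n_z, psf$z_step)
    ax <- 2 * cos(2 * pi * axial_freq_nm * zs)
    vol <- sweep(vol, 3, ax, `*`)
  }
  otf <- stats::fft(ifftshift(vol))
  structure(list(otf = otf, order = as.integer(order),
                 pixel_xy = psf$pixel_xy, z_step = psf$z_step,
                 axial_freq_nm = axial_freq_nm),
            class = "otf3d")
}
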