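#' Simulate a widefield acquisition
#'
#' Convolves the phantom density with the aberrated 3-D PSF (circular
#' convolution on the configured grid) and applies the noise model. With
#' noise off the total signal equals the total phantom mass regardless of
#' (pure-phase) aberration.
#'
#' @param phantom A [make_phantom] result (grid must match `config`).
#' @param aberration [zernike_coeffs] describing the emission-path pupil
#'   aberration.
#' @param config An [optical_config].
#' @param noise A [noise_model] or `NULL` for noiseless data.
#' @param psf Optional precomputed [compute_psf3d] (saves recomputation).
#' @return Real array `(y, x, z)`.
#' @export
simulate_widefield <- function(phantom, aberration = zernike_coeffs(),
                               config = optical_config(), noise = NULL,
                               psf = NULL) {
  check_phantom_grid(phantom, config)
  psf <- psf %||% compute_psf3d(aberration, config)
  img <- Re(conv_fft(phantom$density, psf$volume))
  img[img < 0] <- 0
  apply_noise(img, noise)
}

check_phantom_grid <- function(phantom, config) {
  d <- dim(phantom$density)
  if (d[1] != config$grid_xy || d[2] != config$grid_xy || d[3] != config$n_z) {
    stop(sprintf("phantom grid %dx%dx%d does not match config %dx%dx%d",
                 d[1], d[2], d[3], config$grid_xy, config$grid_xy, config$n_z),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate a raw 3D-SIM acquisition
#'
#' Generates the 15 raw frames per z plane (3 orientations x 5 phases) of a
#' three-beam structured-illumination stack. z-stepping is modelled by
#' moving the object relative to the focal plane while the illumination
#' pattern stays locked to the focal plane, so the axially modulated
#' first-order component combines with the detection PSF into the
#' first-order transfer function used in reconstruction.
#'
#' Excitation-path aberrations do not weaken the coherent pattern; their
#' effect is carried by `pattern$phase_offset_rad` on the +/-1 orders only.
#'
#' @param phantom A [make_phantom] result.
#' @param aberration Emission-path aberration, [zernike_coeffs].
#' @param pattern An [si_pattern].
#' @param config An [optical_config].
#' @param noise A [noise_model] or `NULL`.
#' @param psf Optional precomputed [compute_psf3d].
#' @return A `sim_stack` with `data[y, x, z, phase, orientation]`, the
#'   pattern, config, and the true aberration (simulation metadata).
#' @export
simulate_sim_stack <- function(phantom, aberration = zernike_coeffs(),
                               pattern = si_pattern(),
                               config = optical_config(), noise = NULL,
                               psf = NULL) {
  check_phantom_grid(phantom, config)
  psf <- psf %||% compute_psf3d(aberration, config)
  n <- config$grid_xy; nz <- config$n_z
  n_ph <- length(pattern$phases_rad); n_or <- length(pattern$orientations_deg)
  w <- si_weights(pattern)
  kza <- si_axial_frequency(pattern, config)
  zs <- z_coords(nz, config$z_step)
  kern0 <- stats::fft(ifftshift(psf$volume))
  kern1 <- stats::fft(ifftshift(sweep(psf$volume, 3, cos(2 * pi * kza * zs), `*`)))
  kp <- 1 / pattern$period_nm
  x <- (seq_len(n) - 1) * config$pixel_xy
  dat <- array(0, c(n, n, nz, n_ph, n_or))
  dens_f <- stats::fft(phantom$density)
  c0 <- Re(ifft(dens_f * kern0))
  for (j in seq_len(n_or)) {
    dir <- si_direction(pattern, j)
    u <- outer(x, x, function(yy, xx) dir[1] * xx + dir[2] * yy)
    ramp <- exp(2i * pi * kp * u)
    o1 <- phantom$density * array(ramp, c(n, n, nz))
    o2 <- phantom$density * array(ramp^2, c(n, n, nz))
    c1 <- ifft(stats::fft(o1) * kern1)
    c2 <- ifft(stats::fft(o2) * kern0)
    for (p in seq_len(n_ph)) {
      phi <- pattern$phases_rad[p] + pattern$phase_offset_rad
      fr <- c0 + w$w1 * Re(exp(1i * phi) * c1) + w$w2 * Re(exp(2i * phi) * c2)
      fr[fr < 0] <- 0
      dat[, , , p, j] <- fr
    }
  }
  if (!is.null(noise)) {
    dat <- with_seed(noise$seed, {
      lam <- noise$photons_per_unit * dat + noise$background
      out <- stats::rpois(length(lam), lam)
      if (noise$read_noise_e > 0) out <- out + stats::rnorm(length(lam), 0, noise$read_noise_e)
      array(pmax(out, 0), dim(dat))
    })
  }
  structure(list(data = dat, pattern = pattern, config = config,
                 true_aberration = aberration,
                 noise = noise), class = "sim_stack")
}

#' @export
print.sim_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sim_stack> %d orientations x %d phases x %d z-planes, %d x %d px\n",
              d[5], d[4], d[3], d[1], d[2]))
  invisible(x)
}

#' Extract one raw frame volume
#'
#' @param stack A [simulate_sim_stack] / [read_raw_stack] result.
#' @param orientation,phase 1-based indices.
#' @return Real array `(y, x, z)`.
#' @export
raw_frame <- function(stack, orientation, phase) {
  stack$data[, , , phase, orientation, drop = FALSE][, , , 1, 1]
}
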