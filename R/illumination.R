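#' Three-beam structured-illumination pattern
#'
#' Describes the interference pattern of a central (0-order) beam and two
#' symmetric +/-1-order beams. `period_nm` is the lateral period of the
#' first-order (0 vs +/-1 beat) component, i.e. the beam lateral spatial
#' frequency is `1/period_nm`; the +1/-1 beat adds a second lateral harmonic
#' at `2/period_nm` whose fringe spacing `period_nm/2` is the finest
#' structure in the pattern (341.67 nm for the red channel, hence the
#' default fundamental of 683.34 nm; the green channel uses 546.67 nm).
#'
#' @param period_nm Lateral fundamental period, nm. Must be resolvable:
#'   `period_nm > lambda_ex / (2 NA)` and physically the beams require
#'   `period_nm >= lambda_ex / NA`.
#' @param orientations_deg Pattern orientations (3 for 3D-SIM).
#' @param phases_rad Phase steps (5 equally spaced for 3D-SIM).
#' @param order_intensity_ratio Intensity of each +/-1 beam relative to the
#'   0 beam (the grating is biased so this is ~3, which strengthens the
#'   lateral second harmonic).
#' @param phase_offset_rad Global pattern-phase offset applied to the
#'   +/-1 orders only; models the phase shift that excitation-path
#'   aberrations imprint on the pattern (they do not change its strength).
#' @param axial_period_nm Optional override of the axial modulation period of
#'   the first order; by default it is derived from the three-beam geometry
#'   via [si_axial_frequency].
#' @return An `si_pattern` object.
#' @export
si_pattern <- function(period_nm = 683.34,
                       orientations_deg = c(0, 120, 240),
                       phases_rad = 2 * pi / 5 * 0:4,
                       order_intensity_ratio = 3,
                       phase_offset_rad = 0,
                       axial_period_nm = NULL) {
  stopifnot(is.finite(period_nm), period_nm > 0, order_intensity_ratio >= 0)
  structure(list(period_nm = period_nm,
                 orientations_deg = orientations_deg,
                 phases_rad = phases_rad,
                 order_intensity_ratio = order_intensity_ratio,
                 phase_offset_rad = phase_offset_rad,
                 axial_period_nm = axial_period_nm),
            class = "si_pattern")
}

#' @export
print.si_pattern <- function(x, ...) {
  cat(sprintf(paste0("<si_pattern> period %g nm, %d orientations (%s deg), %d phases,\n",
                     "  +/-1 : 0 intensity ratio %g\n"),
              x$period_nm, length(x$orientations_deg),
              paste(x$orientations_deg, collapse = "/"),
              length(x$phases_rad), x$order_intensity_ratio))
  invisible(x)
}

#' Lateral resolution-enhancement factor
#'
#' `1 + (lambda / (2 NA)) / period`: the ratio of extended to widefield
#' lateral support when the pattern pushes object information out to the
#' widefield cutoff plus twice the beam frequency. The `period_nm` argument
#' is the finest-fringe period of the pattern (half the three-beam
#' fundamental), which is how pattern periods are conventionally quoted.
#'
#' @param wavelength_em Emission wavelength, nm.
#' @param na Numerical aperture.
#' @param period_nm Finest-fringe pattern period, nm.
#' @return Dimensionless enhancement factor.
#' @examples
#' resolution_enhancement(670, 1.2, 341.67)   # 1.818 (red channel)
#' resolution_enhancement(515, 1.2, 273.33)   # 1.78  (green channel)
#' @export
resolution_enhancement <- function(wavelength_em, na, period_nm) {
  stopifnot(wavelength_em > 0, na > 0, period_nm > 0)
  1 + (wavelength_em / (2 * na)) / period_nm
}

#' Axial modulation frequency of the first-order pattern component
#'
#' From the three-beam geometry: the 0 beam travels on axis, the +/-1 beams
#' at angle `theta = asin(lambda_ex / (n * period))`. Their beat along z has
#' frequency `(n / lambda_ex) (1 - cos theta)` (cycles/nm).
#'
#' @param pattern An [si_pattern].
#' @param config An [optical_config].
#' @return Axial frequency, cycles/nm.
#' @export
si_axial_frequency <- function(pattern, config) {
  if (!is.null(pattern$axial_period_nm)) return(1 / pattern$axial_period_nm)
  s <- config$wavelength_ex / (config$n_immersion * pattern$period_nm)
  if (s >= 1) {
    stop(sprintf(
      "pattern period %g nm is below the beam-angle limit lambda/n = %.1f nm",
      pattern$period_nm, config$wavelength_ex / config$n_immersion), call. = FALSE)
  }
  (config$n_immersion / config$wavelength_ex) * (1 - sqrt(1 - s^2))
}

# Unit lateral direction of orientation j (1-based).
si_direction <- function(pattern, orientation) {
  ang <- pattern$orientations_deg[orientation] * pi / 180
  c(cos(ang), sin(ang))
}

# Relative component weights of the pattern intensity, normalized so the
# mean (m = 0) term is 1: intensity = 1 + sum_{m!=0} w_|m| cos(m(...)+...).
# w1 carries the axial cos(2 pi kza z) modulation where used.
si_weights <- function(pattern) {
  r <- pattern$order_intensity_ratio
  c0 <- 1 + 2 * r
  list(w0 = 1, w1 = 2 * sqrt(r) / c0, w2 = r / c0, c0 = c0)
}

#' Structured-illumination intensity volume
#'
#' Three-plane-wave interference intensity for one orientation and phase
#' step, sampled on the configured grid with z measured from the focal
#' plane. The intensity contains a DC term, a first lateral harmonic at
#' `1/period` that is axially modulated at [si_axial_frequency], and a
#' second lateral harmonic at `2/period`. Normalized to unit mean.
#'
#' @param pattern An [si_pattern].
#' @param orientation Orientation index (1-based).
#' @param phase Phase index (1-based).
#' @param config An [optical_config] (grid and sampling).
#' @return Real array `(y, x, z)`, nonnegative, mean 1.
#' @export
si_intensity <- function(pattern, orientation, phase, config) {
  if (orientation < 1 || orientation > length(pattern$orientations_deg)) {
    stop("orientation index out of range", call. = FALSE)
  }
  if (phase < 1 || phase > length(pattern$phases_rad)) {
    stop("phase index out of range", call. = FALSE)
  }
  n <- config$grid_xy
  dir <- si_direction(pattern, orientation)
  kp <- 1 / pattern$period_nm
  kza <- si_axial_frequency(pattern, config)
  w <- si_weights(pattern)
  phi <- pattern$phases_rad[phase] + pattern$phase_offset_rad
  x <- (seq_len(n) - 1) * config$pixel_xy
  u <- outer(x, x, function(yy, xx) dir[1] * xx + dir[2] * yy)  # (row=y, col=x)
  zs <- z_coords(config$n_z, config$z_step)
  vol <- array(0, c(n, n, config$n_z))
  arg <- 2 * pi * kp * u + phi
  lat2 <- w$w2 * cos(2 * arg)
  for (iz in seq_along(zs)) {
    vol[, , iz] <- 1 + w$w1 * cos(arg) * cos(2 * pi * kza * zs[iz]) + lat2
  }
  vol
}

#' Confocal guide-star spot image
#'
#' In-focus intensity of a focused excitation beam through the aberrated
#' pupil: the in-focus excitation PSF slice. Aberration only redistributes
#' the energy (phase-only pupil), so the total is aberration-independent.
#'
#' @param coeffs Aberration as [zernike_coeffs].
#' @param config An [optical_config].
#' @return Real matrix (centered layout), unit total energy.
#' @export
confocal_spot <- function(coeffs = zernike_coeffs(), config = optical_config()) {
  pf <- pupil_field(coeffs, config, wavelength = config$wavelength_ex)
  a <- ifft(pf$field)
  sp <- fftshift(Mod(a)^2)
  sp / (sum(pf$mask) / config$grid_xy^2)
}
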