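#' Signal-to-noise ratio against an adaptive threshold
#'
#' Splits an ROI into object and background with a local adaptive
#' threshold: the Gaussian-weighted neighbourhood mean
#' (sigma = `block_size / 6`) plus `offset`. Because roughly half of any
#' noise field sits above its own local mean, object pixels must further
#' exceed the threshold by a noise guard (5 standard deviations of the
#' below-threshold set). SNR is the mean of the object pixels divided
#' by the standard deviation of the background pixels. An error is raised
#' when no object stands out of the background (e.g. a pure-noise ROI).
#'
#' @param image Real matrix (the ROI around an identifiable object).
#' @param block_size Neighbourhood width for the local threshold, px (odd).
#' @param offset Added to the local threshold.
#' @param min_contrast Required object-over-background contrast, in
#'   background standard deviations.
#' @return Scalar SNR.
#' @export
snr <- function(image, block_size = 51, offset = 0, min_contrast = 4) {
  stopifnot(is.matrix(image), block_size >= 3)
  thr <- gauss_blur(image, sigma = block_size / 6) + offset
  bg0 <- image < thr
  if (!any(bg0)) stop("SNR undefined: background set is empty", call. = FALSE)
  # 5 sd of the (truncation-biased-low) below-threshold set ~ 3.7 true sd:
  # keeps noise false positives out of the object at any ROI size
  guard <- 5 * stats::sd(image[bg0])
  if (!is.finite(guard)) guard <- 0
  obj <- image >= thr + guard
  bg <- !obj
  if (sum(obj) < 5 || !any(bg)) {
    stop("no identifiable object in the ROI", call. = FALSE)
  }
  mu_obj <- mean(image[obj])
  mu_bg <- mean(image[bg])
  sd_bg <- stats::sd(image[bg])
  if (!is.finite(sd_bg) || sd_bg == 0) {
    stop("SNR undefined: degenerate background", call. = FALSE)
  }
  if (mu_obj - mu_bg < min_contrast * sd_bg) {
    stop("no identifiable object in the ROI (contrast below threshold)",
         call. = FALSE)
  }
  mu_obj / sd_bg
}

# Gaussian blur via FFT (circular boundary; ROIs are small and the sigma
# large, which matches the neighbourhood-mean semantics well enough).
gauss_blur <- function(image, sigma) {
  n1 <- nrow(image); n2 <- ncol(image)
  g1 <- stats::dnorm(fft_shift_vec(seq_len(n1) - (floor(n1 / 2) + 1)), sd = sigma)
  g2 <- stats::dnorm(fft_shift_vec(seq_len(n2) - (floor(n2 / 2) + 1)), sd = sigma)
  ker <- outer(g1, g2)
  ker <- ker / sum(ker)
  Re(ifft(stats::fft(image) * stats::fft(ker)))
}

#' Full width at half maximum by Gaussian fit
#'
#' Least-squares fit of `A exp(-(x - mu)^2 / (2 sigma^2)) + c` to a 1-D
#' intensity profile; FWHM = `2 sqrt(2 log 2) sigma`. Invariant to constant
#' offsets by construction.
#'
#' @param profile Numeric vector with a single dominant peak.
#' @param spacing Sample spacing (output is in the same length unit).
#' @return FWHM (length units of `spacing`).
#' @export
fwhm <- function(profile, spacing = 1) {
  stopifnot(is.numeric(profile), length(profile) >= 5, spacing > 0)
  x <- (seq_along(profile) - 1) * spacing
  c0 <- min(profile)
  a0 <- max(profile) - c0
  mu0 <- x[which.max(profile)]
  above <- which(profile - c0 >= a0 / 2)
  s0 <- max((max(above) - min(above)) * spacing / 2.355, spacing / 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)) + C,
                      data = data.frame(x = x, y = profile),
                      start = list(A = a0, mu = mu0, s = s0, C = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("FWHM fit failed: ", conditionMessage(e), call. = FALSE))
  2 * sqrt(2 * log(2)) * abs(stats::coef(fit)[["s"]])
}

#' Lateral/axial FWHM of the brightest spot in a volume
#'
#' Extracts the 1-D profile through the global maximum along x (lateral) or
#' z (axial) and Gaussian-fits it.
#'
#' @param volume Real array `(y, x, z)`.
#' @param pixel_xy,z_step Voxel sizes, nm.
#' @param axis `"x"` or `"z"`.
#' @return FWHM in nm.
#' @export
volume_fwhm <- function(volume, pixel_xy, z_step, axis = c("x", "z")) {
  axis <- match.arg(axis)
  pk <- which(volume == max(volume), arr.ind = TRUE)[1, ]
  if (axis == "x") {
    fwhm(volume[pk[1], , pk[3]], pixel_xy)
  } else {
    fwhm(volume[pk[1], pk[2], ], z_step)
  }
}

# Scale a single-mode coefficient so the wavefront peak-to-valley over the
# pupil equals pv_um.
coeff_for_pv <- function(noll, pv_um, grid_size = 128) {
  unit <- zernike_mode(noll, grid_size)
  pv1 <- wf_pv(unit)
  pv_um / pv1
}

#' Sweep transfer-function overlap amplitudes against aberration strength
#'
#' Reproduces the simulation experiment that quantifies how aberrations
#' degrade the pattern-parameter fit: for each aberration mode and
#' peak-to-valley amplitude, a bead stack is simulated under the aberrated
#' PSF, orders are separated, and the overlap weights are evaluated at the
#' preset (known) pattern frequency and phase. Amplitudes are reported raw
#' and normalized to the flat-wavefront baseline of the same orientation
#' and order.
#'
#' @param config An [optical_config] (small grids keep this fast).
#' @param pattern An [si_pattern].
#' @param pv_amplitudes Peak-to-valley wavefront errors, um (0 included
#'   automatically as baseline).
#' @param modes Named Noll indices of the aberrations to sweep.
#' @param phantom Optional phantom (default: a few beads, seeded).
#' @param seed Seed for the default phantom.
#' @return A `sweep_result` tibble: mode, noll, pv_um, orientation, m,
#'   overlap amplitude and its baseline-normalized value.
#' @export
aberration_sweep <- function(config = optical_config(grid_xy = 64, n_z = 9),
                             pattern = si_pattern(),
                             pv_amplitudes = c(0.2, 0.4, 0.6),
                             modes = c(astigmatism = 5, coma = 8, spherical = 11),
                             phantom = NULL, seed = 42) {
  phantom <- phantom %||% make_phantom("beads", config, n = 6,
                                       diameter_nm = 100, min_sep_nm = 600,
                                       seed = seed)
  psf_flat <- compute_psf3d(zernike_coeffs(), config)
  pvs <- sort(unique(c(0, pv_amplitudes)))
  out <- list()
  for (mi in seq_along(modes)) {
    noll <- modes[[mi]]
    mode_name <- names(modes)[mi] %||% as.character(noll)
    for (pv in pvs) {
      cf <- if (pv == 0) zernike_coeffs() else
        zernike_coeffs(stats::setNames(coeff_for_pv(noll, pv), as.character(noll)))
      st <- simulate_sim_stack(phantom, cf, pattern, config, psf = NULL)
      ord <- separate_orders(st, tukey_gamma = 0.08)
      est <- suppressWarnings(
        estimate_pattern_params(ord, psf_flat, search = FALSE))
      tb <- est$table[est$table$m > 0, ]
      out[[length(out) + 1]] <- tibble::tibble(
        mode = mode_name, noll = noll, pv_um = pv,
        orientation = tb$orientation, m = tb$m,
        overlap = tb$overlap_amplitude)
    }
  }
  res <- dplyr::bind_rows(out)
  base <- dplyr::rename(
    dplyr::select(dplyr::filter(res, .data$pv_um == 0), -"pv_um"),
    baseline = "overlap")
  res <- dplyr::left_join(res, base, by = c("mode", "noll", "orientation", "m"))
  res$overlap_norm <- res$overlap / res$baseline
  res$baseline <- NULL
  class(res) <- c("sweep_result", class(res))
  res
}

#' Plot an aberration sweep
#'
#' @param object A [aberration_sweep] result.
#' @param ... Unused.
#' @return A ggplot: normalized overlap amplitude vs peak-to-valley error,
#'   per mode, orientation and order.
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$pv_um, y = .data$overlap_norm,
                               colour = factor(.data$orientation),
                               linetype = factor(.data$m))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "peak-to-valley wavefront error (µm)",
                  y = "overlap amplitude (normalized)",
                  colour = "orientation", linetype = "order m")
}
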