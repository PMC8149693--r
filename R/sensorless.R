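#' Spatial-frequency image-quality metric configuration
#'
#' The metric weighs high against low spatial frequencies inside the
#' widefield passband. Two Gaussian filters are used: `g_h` (subtracted from
#' 1 in the numerator, emphasizing frequencies above about `NA/(2 lambda)`)
#' and `g_l` (denominator, emphasizing frequencies near zero). Defaults
#' place the `g_h` FWHM at `NA/(2 lambda)` and the `g_l` FWHM at one fifth
#' of that; both are tunable to the image spectrum at hand.
#'
#' @param config An [optical_config] (supplies NA and the emission
#'   wavelength).
#' @param sigma_h,sigma_l Gaussian standard deviations, cycles/nm.
#'   `sigma_h > sigma_l > 0`.
#' @param pixel_xy Image pixel size, nm.
#' @return A `metric_config`.
#' @export
metric_config <- function(config = optical_config(),
                          sigma_h = NULL, sigma_l = NULL,
                          pixel_xy = config$pixel_xy) {
  fwhm_to_sigma <- 1 / (2 * sqrt(2 * log(2)))
  f_h <- config$na / (2 * config$wavelength_em)
  sigma_h <- sigma_h %||% (f_h * fwhm_to_sigma)
  sigma_l <- sigma_l %||% (sigma_h / 5)
  if (!(sigma_h > sigma_l && sigma_l > 0)) {
    stop("need sigma_h > sigma_l > 0", call. = FALSE)
  }
  structure(list(sigma_h = sigma_h, sigma_l = sigma_l,
                 circ_radius = 2 * config$na / config$wavelength_em,
                 pixel_xy = pixel_xy),
            class = "metric_config")
}

#' Spatial-frequency image-quality metric
#'
#' \deqn{M = \frac{\sum |I(u,v)| (1 - g_h(u,v)) \, circ}
#'                {\sum |I(u,v)| \, g_l(u,v) \, circ}}
#' with Gaussian weights `g = exp(-(u^2+v^2)/(2 sigma^2))` and `circ`
#' masking frequencies beyond the widefield cutoff `2 NA / lambda`.
#' Depends on the modulus of the spectrum only, hence is invariant to image
#' translation. Aberrations deplete high frequencies first, lowering M.
#'
#' @param image Real nonnegative matrix (widefield image or ROI).
#' @param cfg A [metric_config].
#' @return Scalar metric value.
#' @export
image_quality_metric <- function(image, cfg) {
  stopifnot(is.matrix(image))
  if (all(image == 0)) stop("metric undefined for an all-zero image", call. = FALSE)
  n1 <- nrow(image); n2 <- ncol(image)
  sp <- Mod(stats::fft(image))
  ku <- fft_freq(n1, cfg$pixel_xy)
  kv <- fft_freq(n2, cfg$pixel_xy)
  k2 <- outer(ku^2, kv^2, `+`)
  circ <- k2 <= cfg$circ_radius^2
  gh <- exp(-k2 / (2 * cfg$sigma_h^2))
  gl <- exp(-k2 / (2 * cfg$sigma_l^2))
  num <- sum(sp * (1 - gh) * circ)
  den <- sum(sp * gl * circ)
  if (den == 0) stop("metric undefined: empty low-frequency support", call. = FALSE)
  num / den
}

#' Peak-value metric for confocal guide-star spots
#'
#' Maximum pixel value after 3x3 mean smoothing (the smoothing suppresses
#' single-pixel noise). Because a confocal spot image is close to the PSF
#' itself, its peak is a direct Strehl-like quality measure.
#'
#' @param spot_image Real nonnegative matrix.
#' @return Scalar metric value.
#' @export
confocal_peak_metric <- function(spot_image) {
  stopifnot(is.matrix(spot_image))
  n1 <- nrow(spot_image); n2 <- ncol(spot_image)
  sm <- spot_image
  if (n1 >= 3 && n2 >= 3) {
    acc <- matrix(0, n1 - 2, n2 - 2)
    for (di in 0:2) for (dj in 0:2) {
      acc <- acc + spot_image[(1 + di):(n1 - 2 + di), (1 + dj):(n2 - 2 + dj)]
    }
    sm <- acc / 9
  }
  max(sm)
}

#' Vertex of the quadratic fit through metric trials
#'
#' Least-squares parabola through `(amplitudes, metric_values)`; the vertex
#' is the optimal correction strength. If the fitted curvature is
#' nonnegative (no maximum) the mode is flagged as not corrected and 0 is
#' returned; a vertex outside the trial range `[-2a, 2a]` (with
#' `a = max(|amplitudes|)`... the half-range used) is clipped to it and
#' flagged.
#'
#' @param amplitudes Trial strengths (>= 3 distinct values).
#' @param metric_values Metric values at the trials.
#' @return List with `vertex`, `corrected` (curvature < 0), `clipped`, and
#'   the fitted coefficients.
#' @export
quadratic_peak <- function(amplitudes, metric_values) {
  if (length(amplitudes) < 3 || length(metric_values) != length(amplitudes)) {
    stop("need >= 3 (amplitude, metric) pairs", call. = FALSE)
  }
  if (length(unique(amplitudes)) < 3) {
    stop("trial amplitudes must be distinct", call. = FALSE)
  }
  fit <- stats::lm(y ~ x + I(x^2), data = data.frame(x = amplitudes, y = metric_values))
  b <- stats::coef(fit)[["x"]]
  c2 <- stats::coef(fit)[["I(x^2)"]]
  if (!is.finite(c2) || c2 >= 0) {
    return(list(vertex = 0, corrected = FALSE, clipped = FALSE,
                coef = stats::coef(fit)))
  }
  v <- -b / (2 * c2)
  lim <- max(abs(amplitudes))
  clipped <- abs(v) > lim
  if (clipped) v <- sign(v) * lim
  list(vertex = v, corrected = TRUE, clipped = clipped, coef = stats::coef(fit))
}

#' Trial schedule for modal sensorless correction
#'
#' @param modes Noll indices to correct. The default {5, 6, 7, 8, 11}
#'   covers both astigmatisms, both comas and primary spherical.
#' @param step_a Trial step, um (0.2 typical; 0.4 for large aberrations).
#' @param n_points Trials per mode: 3 (`-a, 0, a`) or 5 (`-2a..2a`).
#' @param n_iterations Correction iterations.
#' @param step_reduction Factor applied to `step_a` after each iteration.
#' @param roi Optional `c(y0, y1, x0, x1)` region on which the metric is
#'   evaluated (correcting on an ROI maximizes quality there, possibly at
#'   the expense of the rest of the field).
#' @return A `trial_schedule`.
#' @export
trial_schedule <- function(modes = c(5, 6, 7, 8, 11), step_a = 0.2,
                           n_points = 5, n_iterations = 1,
                           step_reduction = 0.5, roi = NULL) {
  if (!n_points %in% c(3, 5)) stop("`n_points` must be 3 or 5", call. = FALSE)
  stopifnot(step_a > 0, n_iterations >= 1)
  structure(list(modes = as.integer(modes), step_a = step_a,
                 n_points = as.integer(n_points),
                 n_iterations = as.integer(n_iterations),
                 step_reduction = step_reduction, roi = roi),
            class = "trial_schedule")
}

trial_strengths <- function(a, n_points) {
  if (n_points == 3) c(-a, 0, a) else c(-2 * a, -a, 0, a, 2 * a)
}

#' Modal sensorless adaptive-optics correction loop
#'
#' For each iteration and each mode, acquires `n_points` trial images at
#' strengths `(-a, 0, a)` or `(-2a, -a, 0, a, 2a)` added to the current
#' correction, evaluates the metric, fits a parabola and takes its vertex
#' as the optimal strength. Within an iteration, modes are evaluated
#' independently from the wavefront state at iteration start and then
#' combined linearly (set `sequential = TRUE` to accumulate mode by mode
#' instead). Iterations repeat with the step reduced by
#' `schedule$step_reduction`, stopping early if the metric of the current
#' correction no longer improves.
#'
#' One iteration over 5 modes with 5 trial strengths issues exactly 25
#' imager calls.
#'
#' @param imager Function `zernike_coeffs -> image matrix`: the microscope
#'   (or simulator) acquiring an image under a trial correction.
#'   Must be deterministic for a fixed seed.
#' @param schedule A [trial_schedule].
#' @param metric Metric function `image -> scalar`
#'   (e.g. `function(img) image_quality_metric(img, cfg)` or
#'   [confocal_peak_metric]).
#' @param sequential Accumulate corrections mode by mode within an
#'   iteration instead of independent evaluation.
#' @return List with `coeffs` (the final correction, [zernike_coeffs]),
#'   `history` (tibble of every trial: iteration, mode, strength, metric,
#'   vertex), `n_acquisitions`, and `metric_final`.
#' @export
modal_correction_loop <- function(imager, schedule = trial_schedule(),
                                  metric, sequential = FALSE) {
  stopifnot(is.function(imager), is.function(metric))
  n_max <- max(schedule$modes)
  corr <- numeric(n_max)
  a <- schedule$step_a
  hist <- list()
  n_acq <- 0L
  eval_metric <- function(img) {
    if (!is.null(schedule$roi)) {
      r <- schedule$roi
      img <- img[r[1]:r[2], r[3]:r[4], drop = FALSE]
    }
    metric(img)
  }
  m_prev <- -Inf
  for (it in seq_len(schedule$n_iterations)) {
    base <- corr
    vertices <- stats::setNames(numeric(length(schedule$modes)),
                                as.character(schedule$modes))
    for (l in schedule$modes) {
      work <- if (sequential) corr else base
      strengths <- trial_strengths(a, schedule$n_points)
      mv <- numeric(length(strengths))
      for (si in seq_along(strengths)) {
        trial <- work
        trial[l] <- trial[l] + strengths[si]
        img <- imager(coeffs_from_dense(trial))
        n_acq <- n_acq + 1L
        mv[si] <- eval_metric(img)
      }
      qp <- quadratic_peak(strengths, mv)
      vertices[as.character(l)] <- qp$vertex
      if (sequential) corr[l] <- corr[l] + qp$vertex
      hist[[length(hist) + 1]] <- tibble::tibble(
        iteration = it, mode = l, strength = strengths, metric = mv,
        vertex = qp$vertex, corrected = qp$corrected, clipped = qp$clipped)
    }
    if (!sequential) {
      corr[schedule$modes] <- corr[schedule$modes] + vertices
    }
    if (it < schedule$n_iterations) {
      # check image for the "image no longer improves" stop rule; the final
      # iteration needs none, so a single iteration costs exactly
      # n_modes * n_points acquisitions
      m_now <- eval_metric(imager(coeffs_from_dense(corr)))
      n_acq <- n_acq + 1L
      if (m_now <= m_prev) break
      m_prev <- m_now
    }
    a <- a * schedule$step_reduction
  }
  list(coeffs = coeffs_from_dense(corr), history = dplyr::bind_rows(hist),
       n_acquisitions = n_acq,
       metric_final = if (is.finite(m_prev)) m_prev else NA_real_)
}

#' Plot a sensorless-AO trial history
#'
#' @param history The `history` tibble from [modal_correction_loop].
#' @return A ggplot: metric vs trial strength per mode and iteration, with
#'   the fitted vertex marked.
#' @export
plot_ao_history <- function(history) {
  ggplot2::ggplot(history,
                  ggplot2::aes(x = .data$strength, y = .data$metric)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$vertex),
                        linetype = 2, colour = "red3") +
    ggplot2::facet_grid(iteration ~ mode,
                        labeller = ggplot2::label_both, scales = "free_y") +
    ggplot2::labs(x = "trial strength (µm)", y = "metric")
}
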