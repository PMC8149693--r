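# Real-space order kernels: K_0 = psf, K_1 = psf * 2 cos(2 pi kza z),
# K_2 = psf (applied at lateral offset 2p). Their transforms are the
# per-order transfer functions used by estimation and reconstruction.
otf_kernels <- function(psf, pattern, config) {
  kza <- si_axial_frequency(pattern, config)
  zs <- z_coords(psf$n_z, psf$z_step)
  k0 <- psf$volume
  k1 <- sweep(psf$volume, 3, 2 * cos(2 * pi * kza * zs), `*`)
  list(`0` = k0, `1` = k1, `2` = k0, kza = kza)
}

kernel_for_order <- function(kernels, m) kernels[[as.character(abs(m))]]

# H_m(k + q) for lateral offset q (cycles/nm): transform of the ifftshifted
# kernel multiplied by the conjugate spatial ramp. Coordinates follow the
# FFT layout (r = index * pixel).
shifted_otf <- function(kernel_centered, q, pixel) {
  n <- dim(kernel_centered)[1]
  k <- kernel_centered
  if (any(q != 0)) {
    # kernels are centered functions: their ramp must use signed coordinates
    # about the centre pixel, otherwise off-grid shifts mis-phase the
    # wrapped (negative-coordinate) half
    x <- (seq_len(n) - (floor(n / 2) + 1)) * pixel
    ramp <- exp(-2i * pi * outer(x * q[2], x * q[1], `+`))  # row = y, col = x
    k <- k * array(as.vector(ramp), dim(k))
  }
  stats::fft(ifftshift(k))
}

# Spectrum of `spec` (unshifted layout) evaluated at k + q.
shifted_spectrum <- function(spec, q, pixel) {
  if (all(q == 0)) return(spec)
  n <- dim(spec)[1]
  x <- (seq_len(n) - 1) * pixel
  ramp <- exp(-2i * pi * outer(x * q[2], x * q[1], `+`))
  stats::fft(ifft(spec) * array(as.vector(ramp), dim(spec)))
}

# Overlap statistics between the zeroth order and order m at trial wave
# vector p: complex weight a (least-squares ratio in the overlap region) and
# the normalized cross-correlation magnitude rho in [0, 1].
overlap_stats <- function(D0, Dm, kernels, m, p, pixel, otf_floor = 0.05,
                          H0 = NULL) {
  q <- m * p
  H0 <- H0 %||% stats::fft(ifftshift(kernel_for_order(kernels, 0)))
  Hms <- shifted_otf(kernel_for_order(kernels, m), q, pixel)
  w <- (Mod(H0) > otf_floor * max(Mod(H0))) &
       (Mod(Hms) > otf_floor * max(Mod(Hms)))
  Dms <- shifted_spectrum(Dm, q, pixel)
  A <- D0 * Hms
  B <- Dms * H0
  cc <- sum(Conj(A[w]) * B[w])
  na <- sum(Mod(A[w])^2)
  nb <- sum(Mod(B[w])^2)
  list(a = cc / na, rho = Mod(cc) / sqrt(na * nb))
}

lateral_ramp <- function(n, pixel, q) {
  x <- (seq_len(n) - 1) * pixel
  exp(-2i * pi * outer(x * q[2], x * q[1], `+`))  # row = y, col = x
}

# kz = 0 plane of the shifted overlap correlation; used for the wave-vector
# search, where it is ~100x cheaper than the full 3-D statistic. `zsum_*`
# are z-sums of the real-space component / kernel, whose 2-D transforms are
# exactly the kz = 0 planes of the 3-D spectra.
overlap_rho_plane <- function(D0_plane, zsum_dm, zsum_km, H0_plane, m, p,
                              pixel, otf_floor) {
  q <- m * p
  n <- nrow(D0_plane)
  ramp <- lateral_ramp(n, pixel, q)
  xs <- (seq_len(n) - (floor(n / 2) + 1)) * pixel
  ramp_k <- exp(-2i * pi * outer(xs * q[2], xs * q[1], `+`))
  Dms <- stats::fft(zsum_dm * ramp)
  Hms <- stats::fft(ifftshift(zsum_km * ramp_k))
  w <- (Mod(H0_plane) > otf_floor * max(Mod(H0_plane))) &
       (Mod(Hms) > otf_floor * max(Mod(Hms)))
  A <- D0_plane * Hms
  B <- Dms * H0_plane
  Mod(sum(Conj(A[w]) * B[w])) / sqrt(sum(Mod(A[w])^2) * sum(Mod(B[w])^2))
}

#' Estimate pattern wave vector, phase and modulation weights
#'
#' For each orientation the lateral pattern wave vector `p_j` is found by
#' maximizing the normalized complex correlation between the zeroth-order
#' component and the shifted second-order component in the region where
#' their transfer functions overlap (the second order is purely lateral and
#' carries twice the wave vector, giving the tightest constraint). The
#' search runs a coarse integer-pixel scan around the nominal wave vector
#' followed by Nelder-Mead sub-pixel refinement. The complex weights
#' `a_{j,m}` are the least-squares amplitude ratios of the shifted
#' components at the optimum (`a_{j,0} = 1` by convention); their magnitudes
#' are the transfer-function overlap amplitudes, and `arg(a_{j,1})` is the
#' global pattern phase.
#'
#' @param orders A [separate_orders] result.
#' @param psf Recon-side [compute_psf3d] on the raw grid (usually
#'   aberration-free: the reconstruction does not know the sample
#'   aberration).
#' @param nominal_p Nominal wave-vector magnitude (cycles/nm); default
#'   `1/period` from the pattern metadata.
#' @param search If `FALSE`, evaluate at the nominal wave vector only
#'   ("preset pattern frequency and phase", as used in aberration sweeps).
#' @param search_px Half-width of the coarse search, in raw-grid frequency
#'   pixels.
#' @param otf_floor Relative transfer-function magnitude defining the
#'   overlap support.
#' @param min_overlap Floor on the overlap amplitude below which the
#'   orientation is flagged as failed (aberrations can prevent the
#'   parameter fit from finding a solution).
#' @return A `pattern_estimate`; `tidy()` it for a per-(orientation, order)
#'   table.
#' @export
estimate_pattern_params <- function(orders, psf, nominal_p = NULL,
                                    search = TRUE, search_px = 2,
                                    otf_floor = 0.05, min_overlap = 0.01) {
  stopifnot(inherits(orders, "separated_orders"))
  cfg <- orders$config
  pat <- orders$pattern
  kernels <- otf_kernels(psf, pat, cfg)
  pixel <- cfg$pixel_xy
  H0f <- stats::fft(ifftshift(kernel_for_order(kernels, 0)))
  n <- dim(orders$components[[1]][[1]])[1]
  dk <- 1 / (n * pixel)
  n_or <- length(orders$components)
  p_list <- vector("list", n_or)
  rows <- list()
  failed <- logical(n_or)
  K2sum <- apply(kernel_for_order(kernels, 2), c(1, 2), sum)  # centered
  for (j in seq_len(n_or)) {
    dirj <- si_direction(pat, j)
    p0 <- (nominal_p %||% (1 / pat$period_nm)) * dirj
    D0 <- orders$components[[j]][["0"]]
    D2 <- orders$components[[j]][["2"]]
    p_best <- p0
    if (search) {
      D0pl <- D0[, , 1]
      H0pl <- H0f[, , 1]
      zsum2 <- apply(ifft(D2), c(1, 2), sum)
      obj <- function(p) overlap_rho_plane(D0pl, zsum2, K2sum, H0pl, 2, p,
                                           pixel, otf_floor)
      offs <- expand.grid(dx = -search_px:search_px, dy = -search_px:search_px)
      vals <- vapply(seq_len(nrow(offs)), function(i) {
        obj(p0 + c(offs$dx[i], offs$dy[i]) * dk)
      }, numeric(1))
      if (max(vals) - min(vals) < 1e-3 * max(vals)) {
        # featureless object spectrum (e.g. a single point source): the
        # shift only changes a global phase, so the correlation magnitude
        # carries no wave-vector information; keep the nominal value
        warning(sprintf(paste0("wave-vector search is degenerate for ",
                               "orientation %d (featureless spectrum); ",
                               "using the nominal wave vector"), j),
                call. = FALSE)
        p_best <- p0
      } else {
        p_best <- p0 + c(offs$dx[which.max(vals)], offs$dy[which.max(vals)]) * dk
        opt <- stats::optim(p_best, function(p) -obj(p), method = "Nelder-Mead",
                            control = list(reltol = 1e-9, maxit = 150,
                                           parscale = c(dk, dk)))
        p_best <- opt$par
      }
    }
    st1 <- overlap_stats(D0, orders$components[[j]][["1"]], kernels, 1,
                         p_best, pixel, otf_floor, H0f)
    st2 <- overlap_stats(D0, D2, kernels, 2, p_best, pixel, otf_floor, H0f)
    amp_max <- suppressWarnings(max(Mod(st1$a), Mod(st2$a), na.rm = TRUE))
    failed[j] <- !is.finite(amp_max) || amp_max < min_overlap
    p_list[[j]] <- p_best
    rows[[length(rows) + 1]] <- tibble::tibble(
      orientation = j, m = c(0L, 1L, 2L),
      a = c(1 + 0i, st1$a, st2$a),
      overlap_amplitude = c(1, Mod(st1$a), Mod(st2$a)),
      correlation = c(1, st1$rho, st2$rho),
      p_mag = sqrt(sum(p_best^2)))
  }
  if (any(failed)) {
    warning(sprintf(
      "overlap amplitude below %.3g for orientation(s) %s; pattern fit unreliable",
      min_overlap, paste(which(failed), collapse = ", ")), call. = FALSE)
  }
  structure(list(p = p_list,
                 phase = vapply(rows, function(r) Arg(r$a[r$m == 1]), numeric(1)),
                 table = dplyr::bind_rows(rows),
                 failed = failed, nominal_p = nominal_p %||% (1 / pat$period_nm)),
            class = "pattern_estimate")
}

#' @export
print.pattern_estimate <- function(x, ...) {
  cat("<pattern_estimate>\n")
  print(tidy.pattern_estimate(x))
  invisible(x)
}

#' Tidy a pattern estimate
#'
#' @param x A `pattern_estimate`.
#' @param ... Unused.
#' @return Tibble with orientation, order, complex weight, overlap amplitude,
#'   normalized correlation and wave-vector magnitude.
#' @export
tidy.pattern_estimate <- function(x, ...) x$table

#' Glance at a pattern estimate
#'
#' @param x A `pattern_estimate`.
#' @param ... Unused.
#' @return One-row-per-orientation tibble: wave vector, phase, failure flag.
#' @export
glance.pattern_estimate <- function(x, ...) {
  tibble::tibble(
    orientation = seq_along(x$p),
    p_x = vapply(x$p, `[`, numeric(1), 1),
    p_y = vapply(x$p, `[`, numeric(1), 2),
    p_mag = vapply(x$p, function(p) sqrt(sum(p^2)), numeric(1)),
    phase_rad = x$phase,
    failed = x$failed)
}
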