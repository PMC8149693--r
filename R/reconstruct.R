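#' Reconstruction parameters
#'
#' Parameters of the generalized Wiener reconstruction.
#'
#' @param wiener_w2 Wiener regularization, as a fraction of the peak of the
#'   assembled denominator (the absolute `w^2` is `wiener_w2 * max(den)`).
#' @param notch_diameter_px Diameter of the top-hat notch suppressing the
#'   overemphasized zero frequency of each shifted transfer-function copy.
#'   Defined in pixels of a 1024-wide output grid and scaled proportionally
#'   (i.e. the physical notch radius is grid-independent).
#' @param notch_ref_grid Reference grid width for the notch definition.
#' @param tukey_gamma Taper fraction of the real-space Tukey window applied
#'   to the raw frames before transforming.
#' @param apod_axy,apod_az,apod_n Apodization parameters of the modified
#'   triangle function
#'   `A(k) = [(1 - a_xy k_xy / k_cutoff_xy)(1 - a_z |k_z| / k_cutoff_z)]^n`
#'   with cutoffs `k_cutoff_xy = 4 NA / lambda`, `k_cutoff_z = NA^2 / lambda`
#'   and both factors clipped at 0. Allowed ranges: `a_xy, a_z` in [0.5, 1],
#'   `n` in [0.5, 2].
#' @param upsample Lateral output-grid factor over the raw grid (the raw
#'   data are Fourier-embedded into the finer output grid before assembly).
#' @param min_overlap Components whose estimated weight magnitude falls
#'   below this are dropped from the assembly (their parameters are
#'   unreliable).
#' @return A `recon_params` object.
#' @export
recon_params <- function(wiener_w2 = 1e-4, notch_diameter_px = 9,
                         notch_ref_grid = 1024, tukey_gamma = 0.08,
                         apod_axy = 1, apod_az = 1, apod_n = 1,
                         upsample = 2, min_overlap = 0.01) {
  if (!is.finite(wiener_w2) || wiener_w2 <= 0) {
    stop("`wiener_w2` must be positive", call. = FALSE)
  }
  stopifnot(apod_axy >= 0.5, apod_axy <= 1, apod_az >= 0.5, apod_az <= 1,
            apod_n >= 0.5, apod_n <= 2)
  structure(list(wiener_w2 = wiener_w2, notch_diameter_px = notch_diameter_px,
                 notch_ref_grid = notch_ref_grid, tukey_gamma = tukey_gamma,
                 apod_axy = apod_axy, apod_az = apod_az, apod_n = apod_n,
                 upsample = as.integer(upsample), min_overlap = min_overlap),
            class = "recon_params")
}

#' Frequency-domain filters of the reconstruction
#'
#' Builds, for a given output grid, the three filters of the generalized
#' Wiener reconstruction: the top-hat notch `G` (as a function of the
#' lateral offset of each transfer-function copy), the real-space Tukey
#' window `T`, and the apodization `A`.
#'
#' @param params A [recon_params].
#' @param dims Output grid dimensions `(ny, nx, nz)`.
#' @param pixel_xy,z_step Output voxel sizes, nm.
#' @param na,wavelength Numerical aperture and emission wavelength (nm) for
#'   the apodization cutoffs.
#' @return List with `notch(q)` (function of lateral offset, cycles/nm,
#'   returning the 0/1 notch volume centred at `-q`), `tukey` (real-space
#'   window volume), `apod` (apodization volume, unshifted layout) and the
#'   notch radius / cutoff frequencies.
#' @export
build_filters <- function(params, dims, pixel_xy, z_step, na, wavelength) {
  kg <- kgrid_xy(dims[1], pixel_xy)
  kz <- fft_freq(dims[3], z_step)
  r_notch <- (params$notch_diameter_px / 2) / (params$notch_ref_grid * pixel_xy)
  k_cut_xy <- 4 * na / wavelength
  k_cut_z <- na^2 / wavelength
  lat <- pmax(1 - params$apod_axy * kg$kr / k_cut_xy, 0)
  axi <- pmax(1 - params$apod_az * abs(kz) / k_cut_z, 0)
  apod <- outer(lat, axi)^params$apod_n
  dim(apod) <- dims
  notch <- function(q = c(0, 0)) {
    g2 <- sqrt((kg$kx + q[1])^2 + (kg$ky + q[2])^2) <= r_notch
    array(as.numeric(g2), dims)
  }
  list(notch = notch, tukey = tukey_volume(dims, params$tukey_gamma),
       apod = apod, r_notch = r_notch,
       k_cutoff_xy = k_cut_xy, k_cutoff_z = k_cut_z)
}

#' Generalized Wiener 3D-SIM reconstruction
#'
#' Assembles the separated, shifted order components into the
#' super-resolved spectrum
#' \deqn{S(k) = \frac{\sum_{j,m} a_{j,m} \{H_m(k+mp_j)[1-G(k+mp_j)]\}^*
#'   D_{j,m}(k+mp_j)}{\sum_{j,m} |H_m(k+mp_j)[1-G(k+mp_j)]|^2 + w^2} A(k)}
#' and returns the real part of its inverse transform. The complex weights
#' enter as a matched filter (conjugated) in the numerator and as
#' `|a_{j,m}|^2` in the denominator, so each order contributes a flat unit
#' response across the union support; for weights normalized near unity
#' this coincides with an unweighted denominator. Components are
#' Fourier-embedded into the finer output grid, shifted by their wave
#' vectors with sub-pixel spatial ramps, matched against the per-order
#' transfer functions, notch-filtered, Wiener-divided and apodized. The
#' Tukey window enters as the real-space taper applied during order
#' separation.
#'
#' @param orders A [separate_orders] result.
#' @param estimate A [estimate_pattern_params] result.
#' @param params A [recon_params].
#' @param psf_hi Optional [compute_psf3d] on the output grid (aberration-free
#'   by default).
#' @param orientations Subset of orientations to assemble (default: all).
#' @param include_orders Orders `m >= 0` to include, e.g. `0:2` (negative
#'   orders follow by conjugate symmetry). Dropping `1:2` reduces the
#'   reconstruction to a Wiener-deconvolved widefield image.
#' @return A `sim_recon` object: `volume` (real array on the output grid),
#'   voxel sizes, and the effective filters' metadata.
#' @export
wiener_reconstruct <- function(orders, estimate, params = recon_params(),
                               psf_hi = NULL, orientations = NULL,
                               include_orders = 0:2) {
  stopifnot(inherits(orders, "separated_orders"),
            inherits(estimate, "pattern_estimate"))
  cfg <- orders$config
  up <- params$upsample
  n_lo <- dim(orders$components[[1]][[1]])[1]
  nz <- dim(orders$components[[1]][[1]])[3]
  n_hi <- n_lo * up
  pixel_hi <- cfg$pixel_xy / up
  cfg_hi <- optical_config(wavelength_em = cfg$wavelength_em,
                           wavelength_ex = cfg$wavelength_ex,
                           na = cfg$na, n_immersion = cfg$n_immersion,
                           pixel_xy = pixel_hi, z_step = cfg$z_step,
                           grid_xy = n_hi, n_z = nz)
  psf_hi <- psf_hi %||% compute_psf3d(zernike_coeffs(), cfg_hi)
  kernels <- otf_kernels(psf_hi, orders$pattern, cfg_hi)
  filt <- build_filters(params, c(n_hi, n_hi, nz), pixel_hi, cfg$z_step,
                        cfg$na, cfg$wavelength_em)
  dims_hi <- c(n_hi, n_hi, nz)
  num <- array(0 + 0i, dims_hi)
  den <- array(0, dims_hi)
  atab <- estimate$table
  orientations <- orientations %||% seq_along(orders$components)
  for (j in orientations) {
    pj <- estimate$p[[j]]
    for (m_abs in include_orders) {
      a <- if (m_abs == 0) 1 + 0i else atab$a[atab$orientation == j & atab$m == m_abs]
      if (m_abs > 0 && Mod(a) < params$min_overlap) next
      for (sgn in if (m_abs == 0) 1 else c(1, -1)) {
        m <- sgn * m_abs
        am <- if (sgn > 0) a else Conj(a)
        q <- m * pj
        Dlo <- orders$components[[j]][[as.character(m)]]
        Dhi <- embed_spectrum(Dlo, dims_hi)
        Ds <- shifted_spectrum(Dhi, q, pixel_hi)
        Hs <- shifted_otf(kernel_for_order(kernels, m), q, pixel_hi)
        Hn <- Hs * (1 - filt$notch(q))
        num <- num + Conj(am) * Conj(Hn) * Ds
        den <- den + Mod(am)^2 * Mod(Hn)^2
        if (m_abs == 0) break
      }
    }
  }
  w2 <- params$wiener_w2 * max(den)
  spec <- num / (den + w2) * filt$apod
  vol <- Re(ifft(spec))
  structure(list(volume = vol, pixel_xy = pixel_hi, z_step = cfg$z_step,
                 params = params, estimate = estimate,
                 k_cutoff_xy = filt$k_cutoff_xy, k_cutoff_z = filt$k_cutoff_z,
                 w2_abs = w2),
            class = "sim_recon")
}

#' @export
print.sim_recon <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("<sim_recon> %d x %d x %d, pixel %g nm, z-step %g nm\n",
              d[1], d[2], d[3], x$pixel_xy, x$z_step))
  invisible(x)
}

#' Reconstruct a raw SIM stack end to end
#'
#' Convenience pipeline: order separation, pattern-parameter estimation and
#' generalized Wiener assembly with default settings.
#'
#' @param stack A raw SIM stack.
#' @param params A [recon_params].
#' @param search Passed to [estimate_pattern_params].
#' @return A list with `recon` ([wiener_reconstruct] result) and `estimate`.
#' @export
sim_reconstruct <- function(stack, params = recon_params(), search = TRUE) {
  orders <- separate_orders(stack, tukey_gamma = params$tukey_gamma)
  psf <- compute_psf3d(zernike_coeffs(), stack$config)
  est <- estimate_pattern_params(orders, psf, search = search)
  rec <- wiener_reconstruct(orders, est, params)
  list(recon = rec, estimate = est)
}
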