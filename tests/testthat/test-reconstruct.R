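test_that("reconstruction filters match their definitions", {
  p <- recon_params()
  f <- build_filters(p, c(64, 64, 9), 44.5, 200, 1.2, 670)
  # apodization is 1 at the origin and 0 at the lateral cutoff (a_xy = 1)
  expect_equal(f$apod[1, 1, 1], 1)
  kx <- aosim:::fft_freq(64, 44.5)
  at_cut <- which.min(abs(kx - f$k_cutoff_xy))
  expect_lt(f$apod[1, at_cut, 1], 0.02)
  expect_equal(f$k_cutoff_xy, 4 * 1.2 / 670)
  expect_equal(f$k_cutoff_z, 1.2^2 / 670)
  # notch: 1 in a disk around the (shifted) origin, 0 elsewhere
  g0 <- f$notch(c(0, 0))
  expect_equal(g0[1, 1, 1], 1)
  expect_equal(sum(g0[, , 1]), sum(g0[, , 5]))  # lateral cylinder
  expect_equal(g0[1, 32, 1], 0)
  # Tukey window: plateau 1, corners 0
  tw <- aosim:::tukey_volume(c(64, 64, 9), 0.08)
  expect_equal(tw[32, 32, 5], 1)
  expect_equal(tw[1, 1, 1], 0)
  expect_equal(aosim:::tukey_window(100, 0)[1], 1)
  expect_error(recon_params(wiener_w2 = 0), "positive")
  expect_error(recon_params(apod_axy = 0.2))
})

recon_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- small_config()
    ph <- make_phantom("beads", cfg, n = 1, diameter_nm = 50, seed = 3,
                       margin_frac = 0.45)
    st <- simulate_sim_stack(ph, zernike_coeffs(), si_pattern(), cfg)
    ord <- separate_orders(st, tukey_gamma = 0.08)
    # a single point source cannot constrain the wave vector; use the
    # preset-frequency protocol
    est <- estimate_pattern_params(ord, flat_psf_64(), search = FALSE)
    cache <<- list(cfg = cfg, ph = ph, ord = ord, est = est)
    cache
  }
})

test_that("dropping the side orders reduces to Wiener widefield deconvolution", {
  fx <- recon_fixture()
  rec0 <- wiener_reconstruct(fx$ord, fx$est, recon_params(),
                             include_orders = 0)
  # manual Wiener deconvolution of the zeroth order with the same filters
  p <- recon_params()
  n_hi <- 128; nz <- 9
  cfg_hi <- optical_config(pixel_xy = fx$cfg$pixel_xy / 2, grid_xy = n_hi,
                           n_z = nz)
  psf_hi <- compute_psf3d(zernike_coeffs(), cfg_hi)
  H0 <- stats::fft(aosim:::ifftshift(psf_hi$volume))
  filt <- build_filters(p, c(n_hi, n_hi, nz), cfg_hi$pixel_xy, 200, 1.2, 670)
  num <- 0
  for (j in 1:3) {
    D <- aosim:::embed_spectrum(fx$ord$components[[j]][["0"]], c(n_hi, n_hi, nz))
    num <- num + Conj(H0 * (1 - filt$notch(c(0, 0)))) * D
  }
  den <- 3 * Mod(H0 * (1 - filt$notch(c(0, 0))))^2
  w2 <- p$wiener_w2 * max(den)
  ref <- Re(aosim:::ifft(num / (den + w2) * filt$apod))
  expect_lt(max(abs(rec0$volume - ref)) / max(ref), 1e-8)
})

test_that("the full reconstruction sharpens laterally and axially", {
  fx <- recon_fixture()
  rec <- wiener_reconstruct(fx$ord, fx$est, recon_params())
  wf <- simulate_widefield(fx$ph, zernike_coeffs(), fx$cfg)
  lat_wf <- half_max_width(wf, fx$cfg$pixel_xy, "x")
  lat_sr <- half_max_width(rec$volume, rec$pixel_xy, "x")
  expect_gt(lat_wf / lat_sr, 1.6)
  expect_lt(half_max_width(rec$volume, 200, "z"), half_max_width(wf, 200, "z"))
})

test_that("the effective transfer function widens by about the enhancement factor", {
  fx <- recon_fixture()
  rec <- wiener_reconstruct(fx$ord, fx$est, recon_params())
  support <- function(vol, pixel) {
    sp <- Mod(stats::fft(vol))[1, , 1]
    kx <- aosim:::fft_freq(length(sp), pixel)
    max(abs(kx[sp > 1e-3 * max(sp)]))
  }
  wf <- simulate_widefield(fx$ph, zernike_coeffs(), fx$cfg)
  widen <- support(rec$volume, rec$pixel_xy) / support(wf, fx$cfg$pixel_xy)
  enh <- resolution_enhancement(670, 1.2, si_pattern()$period_nm / 2)
  expect_gt(widen, enh * 0.9)
  expect_lt(widen, enh * 1.25)
})

test_that("reconstruction is linear in the data for a fixed estimate", {
  cfg <- small_config(48, 5)
  pat <- si_pattern()
  pa <- make_phantom("beads", cfg, n = 1, diameter_nm = 60, seed = 21,
                     margin_frac = 0.35)
  pb <- make_phantom("beads", cfg, n = 1, diameter_nm = 60, seed = 33,
                     margin_frac = 0.35)
  psum <- pa; psum$density <- pa$density + pb$density
  psf <- compute_psf3d(zernike_coeffs(), cfg)
  run <- function(ph) {
    st <- simulate_sim_stack(ph, zernike_coeffs(), pat, cfg)
    separate_orders(st, tukey_gamma = 0.08)
  }
  oa <- run(pa); ob <- run(pb); os <- run(psum)
  est <- estimate_pattern_params(oa, psf, search = FALSE)
  pr <- recon_params()
  ra <- wiener_reconstruct(oa, est, pr)$volume
  rb <- wiener_reconstruct(ob, est, pr)$volume
  rs <- wiener_reconstruct(os, est, pr)$volume
  expect_lt(max(abs(rs - ra - rb)) / max(abs(rs)), 0.01)
})

test_that("heavy Wiener regularization shrinks the output monotonically", {
  fx <- recon_fixture()
  amps <- vapply(c(1e-4, 1e-2, 1, 100), function(w2) {
    max(abs(wiener_reconstruct(fx$ord, fx$est,
                               recon_params(wiener_w2 = w2))$volume))
  }, numeric(1))
  expect_true(all(diff(amps) < 0))
})
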