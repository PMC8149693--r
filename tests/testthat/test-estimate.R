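make_stack_64 <- function(aberration = zernike_coeffs(), noise = NULL,
                          phase_offset = 0, seed = 7) {
  cfg <- small_config()
  pat <- si_pattern(phase_offset_rad = phase_offset)
  ph <- make_phantom("beads", cfg, n = 4, diameter_nm = 100,
                     min_sep_nm = 900, seed = seed)
  simulate_sim_stack(ph, aberration, pat, cfg, noise = noise)
}

test_that("wave vector, phase and weights are recovered on noise-free data", {
  st <- make_stack_64(phase_offset = 0.3)
  ord <- separate_orders(st, tukey_gamma = 0)
  est <- estimate_pattern_params(ord, flat_psf_64())
  p_true <- 1 / st$pattern$period_nm
  r <- st$pattern$order_intensity_ratio
  for (j in 1:3) {
    expect_rel_equal(sqrt(sum(est$p[[j]]^2)), p_true, 0.002)
    expect_lt(abs(est$phase[j] - 0.3), 0.02)
  }
  tb <- tidy(est)
  expect_equal(tb$overlap_amplitude[tb$m == 1],
               rep(sqrt(r) / (2 * (1 + 2 * r)), 3), tolerance = 0.02)
  expect_equal(tb$overlap_amplitude[tb$m == 2],
               rep(r / (2 * (1 + 2 * r)), 3), tolerance = 0.02)
  expect_false(any(glance(est)$failed))
})

test_that("aberrations depress the overlap amplitudes", {
  st_flat <- make_stack_64()
  st_ab <- make_stack_64(zernike_coeffs(
    stats::setNames(aosim:::coeff_for_pv(5, 0.3), "5")))
  psf <- flat_psf_64()
  a_flat <- tidy(estimate_pattern_params(separate_orders(st_flat, 0), psf,
                                         search = FALSE))
  a_ab <- tidy(estimate_pattern_params(separate_orders(st_ab, 0), psf,
                                       search = FALSE))
  for (j in 1:3) for (mm in 1:2) {
    f <- a_flat$overlap_amplitude[a_flat$orientation == j & a_flat$m == mm]
    b <- a_ab$overlap_amplitude[a_ab$orientation == j & a_ab$m == mm]
    expect_lt(b, f)
  }
})

test_that("vanishing overlap is reported as failure", {
  # side beams off: no m != 0 signal at all
  cfg <- small_config()
  ph <- make_phantom("beads", cfg, n = 4, min_sep_nm = 900, seed = 7)
  st0 <- simulate_sim_stack(ph, zernike_coeffs(),
                            si_pattern(order_intensity_ratio = 0), cfg)
  ord <- separate_orders(st0, tukey_gamma = 0)
  expect_warning(est <- estimate_pattern_params(ord, flat_psf_64(),
                                                search = FALSE),
                 "unreliable")
  expect_true(all(glance(est)$failed))
})

test_that("wave-vector recovery stays within 1% median error under noise", {
  errs <- c()
  for (s in 1:8) {
    st <- make_stack_64(noise = noise_model(photons_per_unit = 1e5,
                                            read_noise_e = 2, background = 5,
                                            seed = s),
                        seed = s)
    ord <- separate_orders(st, tukey_gamma = 0.08)
    est <- estimate_pattern_params(ord, flat_psf_64())
    p_true <- 1 / st$pattern$period_nm
    errs <- c(errs, vapply(est$p, function(p) {
      abs(sqrt(sum(p^2)) - p_true) / p_true
    }, numeric(1)))
  }
  expect_lt(stats::median(errs), 0.01)
})
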