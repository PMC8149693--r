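test_that("widefield image peaks at the bead and conserves photons", {
  cfg <- small_config()
  ph <- make_phantom("beads", cfg, n = 1, diameter_nm = 100, seed = 2,
                     margin_frac = 0.45)
  img <- simulate_widefield(ph, zernike_coeffs(), cfg)
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  ctr <- c(ph$positions$y_nm / cfg$pixel_xy + 32.5,
           ph$positions$x_nm / cfg$pixel_xy + 32.5)
  expect_lt(max(abs(pk[1:2] - ctr)), 1.5)
  # photon conservation under aberration, noise off
  img_ab <- simulate_widefield(ph, zernike_coeffs(c(`7` = 0.3)), cfg)
  expect_equal(sum(img_ab), sum(img), tolerance = 1e-6)
  expect_equal(sum(img), sum(ph$density), tolerance = 1e-6)
})

test_that("astigmatic bead images elongate along axes 45 degrees apart through focus", {
  cfg <- optical_config(grid_xy = 64, n_z = 11)
  # point emitter exactly at the volume centre
  ph <- make_phantom("beads", cfg, n = 1, diameter_nm = 100, seed = 2)
  ph$density[] <- 0
  ph$density[33, 33, 6] <- 1
  img <- simulate_widefield(ph, zernike_coeffs(c(`5` = 0.25)), cfg)
  orient <- function(sl) {
    sl <- pmax(sl - 0.05 * max(sl), 0)
    w <- sl / sum(sl)
    x <- matrix(seq_len(64), 64, 64, byrow = TRUE); y <- t(x)
    mx <- sum(w * x); my <- sum(w * y)
    cxx <- sum(w * (x - mx)^2); cyy <- sum(w * (y - my)^2)
    cxy <- sum(w * (x - mx) * (y - my))
    0.5 * atan2(2 * cxy, cxx - cyy)
  }
  # emitter sits in plane 6: compare symmetric defocus planes +/- 400 nm
  a_lo <- orient(img[, , 4])
  a_hi <- orient(img[, , 8])
  dang <- abs(a_lo - a_hi) %% pi
  dang <- min(dang, pi - dang)
  expect_equal(dang, pi / 2, tolerance = 0.25)
})

test_that("SIM stacks have 15 frames per plane that average to widefield", {
  cfg <- small_config()
  ph <- make_phantom("beads", cfg, n = 3, min_sep_nm = 900, seed = 4)
  pat <- si_pattern()
  st <- simulate_sim_stack(ph, zernike_coeffs(), pat, cfg)
  d <- dim(st$data)
  expect_equal(d[4] * d[5], 15)
  wf <- simulate_widefield(ph, zernike_coeffs(), cfg)
  for (j in 1:3) {
    mj <- apply(st$data[, , , , j], 1:3, mean)
    expect_lt(max(abs(mj - wf)) / max(wf), 1e-6)
  }
  # uniform pattern (side beams off): all 15 frames identical
  st0 <- simulate_sim_stack(ph, zernike_coeffs(),
                            si_pattern(order_intensity_ratio = 0), cfg)
  rng <- apply(st0$data, 1:3, function(v) diff(range(v)))
  expect_lt(max(rng), 1e-10)
})

test_that("the forward model is linear and seeded noise reproducible", {
  cfg <- small_config(48, 5)
  pa <- make_phantom("beads", cfg, n = 2, min_sep_nm = 700, seed = 1)
  pb <- make_phantom("beads", cfg, n = 2, min_sep_nm = 700, seed = 9)
  pat <- si_pattern()
  psum <- pa
  psum$density <- pa$density + pb$density
  sa <- simulate_sim_stack(pa, zernike_coeffs(), pat, cfg)
  sb <- simulate_sim_stack(pb, zernike_coeffs(), pat, cfg)
  ss <- simulate_sim_stack(psum, zernike_coeffs(), pat, cfg)
  expect_equal(ss$data, sa$data + sb$data, tolerance = 1e-9)
  nz <- noise_model(photons_per_unit = 500, read_noise_e = 2, seed = 11)
  n1 <- simulate_sim_stack(pa, zernike_coeffs(), pat, cfg, noise = nz)
  n2 <- simulate_sim_stack(pa, zernike_coeffs(), pat, cfg, noise = nz)
  expect_identical(n1$data, n2$data)
  n3 <- simulate_sim_stack(pa, zernike_coeffs(), pat, cfg,
                           noise = noise_model(photons_per_unit = 500, seed = 12))
  expect_false(identical(n1$data, n3$data))
})

test_that("Shack-Hartmann simulation reproduces geometric spot displacements", {
  geo <- sh_geometry()
  grid <- 8 * geo$lenslets_across
  ref <- simulate_shwfs_frame(synthesize_wavefront(zernike_coeffs(), grid), geo)
  expect_true(all(is.na(ref$true_disp_x_um[!ref$valid_mask]) |
                    abs(ref$true_disp_x_um[!ref$valid_mask]) >= 0))
  expect_lt(max(abs(ref$true_disp_x_um[ref$valid_mask])), 1e-3)
  # pure tilt: uniform displacement f_ML * slope
  w2 <- synthesize_wavefront(zernike_coeffs(c(`2` = 0.3)), grid)
  fr <- simulate_shwfs_frame(w2, geo)
  slope <- 0.3 * 2 / (geo$pupil_diameter_mm * 1000 / 2)  # d(2 rho)/dr * c
  expect_rel_equal(mean(fr$true_disp_x_um[fr$valid_mask]),
                   geo$lenslet_focal_mm * 1000 * slope, 0.02)
  expect_lt(stats::sd(fr$true_disp_x_um[fr$valid_mask]), 1e-9)
  # defocus: displacement linear in radius
  w4 <- synthesize_wavefront(zernike_coeffs(c(`4` = 0.3)), grid)
  f4 <- simulate_shwfs_frame(w4, geo)
  lc <- aosim:::lenslet_centers(geo)
  ok <- f4$valid_mask
  fitx <- stats::lm(dx ~ x, data = data.frame(dx = f4$true_disp_x_um[ok],
                                              x = lc$cx_um[ok]))
  expect_gt(summary(fitx)$r.squared, 0.999)
})
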