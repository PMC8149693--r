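test_that("flat-wavefront PSF is symmetric with the diffraction-limited width", {
  cfg <- small_config(128, 9)
  psf <- compute_psf3d(zernike_coeffs(), cfg)
  v <- psf$volume
  expect_equal(sum(v), 1, tolerance = 1e-9)
  mid <- v[, , 5]
  # 180-degree rotational symmetry of the in-focus slice
  rot <- mid[nrow(mid):1, ncol(mid):1]
  # centre pixel of an even grid is off by one under rotation; compare on
  # the common centred part
  expect_lt(max(abs(mid[2:128, 2:128] - rot[1:127, 1:127])) / max(mid), 1e-6)
  # lateral FWHM ~ lambda / (2 NA) = 279 nm
  expect_rel_equal(half_max_width(v, cfg$pixel_xy, "x"),
                   cfg$wavelength_em / (2 * cfg$na), 0.1)
})

test_that("pure-phase aberrations conserve energy and reduce the peak", {
  cfg <- small_config(64, 9)
  peaks <- c()
  for (amp in c(0, 0.1, 0.25, 0.5)) {
    psf <- compute_psf3d(zernike_coeffs(c(`11` = amp)), cfg)
    expect_equal(sum(psf$volume), 1, tolerance = 1e-6)
    peaks <- c(peaks, max(psf$volume))
  }
  # Strehl-like monotone decrease with aberration strength
  expect_true(all(diff(peaks) < 0))
})

test_that("coma extends the axial profile of the PSF", {
  cfg <- small_config(64, 15)
  flat <- compute_psf3d(zernike_coeffs(), cfg)
  coma <- compute_psf3d(zernike_coeffs(c(`8` = 0.3)), cfg)
  axial_w <- function(psf) {
    pk <- which(psf$volume == max(psf$volume), arr.ind = TRUE)[1, ]
    pr <- psf$volume[pk[1], pk[2], ]
    sum(pr >= max(pr) / 2)
  }
  expect_gt(axial_w(coma), axial_w(flat) - 1)
  zc <- function(psf) {  # second-moment axial extent at the lateral peak
    pk <- which(psf$volume == max(psf$volume), arr.ind = TRUE)[1, ]
    pr <- psf$volume[pk[1], pk[2], ]
    z <- seq_along(pr)
    sqrt(sum(pr * (z - sum(pr * z) / sum(pr))^2) / sum(pr))
  }
  expect_gt(zc(coma), zc(flat))
})

test_that("zeroth-order OTF is normalized, Hermitian and band-limited", {
  cfg <- small_config(64, 9)
  psf <- compute_psf3d(zernike_coeffs(c(`6` = 0.15)), cfg)
  otf <- compute_otf3d(psf, 0)
  expect_equal(Mod(otf$otf[1, 1, 1]), 1, tolerance = 1e-9)
  expect_lt(abs(Im(otf$otf[1, 1, 1])), 1e-12)
  # Hermitian symmetry H(-k) = conj(H(k))
  idx <- function(n) c(1, n:2)
  o <- otf$otf
  expect_lt(max(Mod(o[idx(64), idx(64), idx(9)] - Conj(o))), 1e-10)
  # support bounded by the widefield cutoff 2 NA / lambda
  kg <- aosim:::kgrid_xy(64, cfg$pixel_xy)
  outside <- kg$kr > 2 * cfg$na / cfg$wavelength_em * 1.02
  expect_lt(max(Mod(o[, , 1][outside])), 1e-3)
})

test_that("first-order OTF is the two-copy axial-shift construction", {
  cfg <- small_config(32, 9)
  psf <- compute_psf3d(zernike_coeffs(), cfg)
  kza <- 6e-4
  h1 <- compute_otf3d(psf, 1, axial_freq_nm = kza)
  # at kz = 0 the two copies coincide: H1 = 2 * H0 evaluated at kz = +/-kza,
  # where H0 at the off-grid axial frequency is the explicit z-sum
  zs <- aosim:::z_coords(9, cfg$z_step)
  copy_at <- function(sgn) {
    m <- apply(sweep(psf$volume, 3, exp(sgn * 2i * pi * kza * zs), `*`),
               c(1, 2), sum)
    stats::fft(aosim:::ifftshift(m))
  }
  both <- copy_at(+1) + copy_at(-1)
  expect_lt(max(Mod(h1$otf[, , 1] - both)), 1e-8)
  # for the z-symmetric unaberrated PSF the two copies coincide at kz = 0
  expect_lt(max(Mod(copy_at(+1) - copy_at(-1))) / max(Mod(both)), 0.02)
  expect_error(compute_otf3d(psf, 3), "unknown order")
  expect_error(compute_otf3d(psf, 1), "axial_freq_nm")
})
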