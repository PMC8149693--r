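test_that("the spatial-frequency metric is translation-invariant and vanishes for flat images", {
  cfg <- small_config()
  mcfg <- metric_config(cfg)
  set.seed(1)
  img <- matrix(stats::runif(64 * 64), 64)
  img_shift <- img[c(11:64, 1:10), c(30:64, 1:29)]
  expect_lt(abs(image_quality_metric(img, mcfg) -
                  image_quality_metric(img_shift, mcfg)), 1e-10)
  expect_equal(image_quality_metric(matrix(3, 64, 64), mcfg), 0,
               tolerance = 1e-10)
  expect_error(image_quality_metric(matrix(0, 16, 16), mcfg), "all-zero")
  expect_error(metric_config(cfg, sigma_h = 1e-4, sigma_l = 2e-4), "sigma_h")
})

test_that("aberration lowers the metric of a bead image", {
  cfg <- small_config()
  ph <- make_phantom("beads", cfg, n = 3, min_sep_nm = 900, seed = 5)
  mcfg <- metric_config(cfg)
  mid <- floor(cfg$n_z / 2) + 1
  m_flat <- image_quality_metric(
    simulate_widefield(ph, zernike_coeffs(), cfg)[, , mid], mcfg)
  m_ab <- image_quality_metric(
    simulate_widefield(ph, zernike_coeffs(c(`5` = 0.2)), cfg)[, , mid], mcfg)
  expect_gt(m_flat, m_ab)
})

test_that("the metric is unimodal in a single mode amplitude", {
  cfg <- small_config(48, 5)
  ph <- make_phantom("beads", cfg, n = 2, min_sep_nm = 800, seed = 5)
  mcfg <- metric_config(cfg)
  amps <- seq(-0.4, 0.4, length.out = 17)
  m <- vapply(amps, function(a) {
    img <- simulate_widefield(ph, zernike_coeffs(c(`6` = a)), cfg)[, , 3]
    image_quality_metric(img, mcfg)
  }, numeric(1))
  pk <- which.max(m)
  expect_true(all(diff(m[seq_len(pk)]) > 0))
  expect_true(all(diff(m[pk:length(m)]) < 0))
})

test_that("the confocal peak metric behaves like a Strehl measure", {
  cfg <- small_config(48, 3)
  flat <- confocal_spot(zernike_coeffs(), cfg)
  coma <- confocal_spot(zernike_coeffs(c(`8` = 0.3)), cfg)
  expect_gt(confocal_peak_metric(flat), confocal_peak_metric(coma))
  expect_equal(confocal_peak_metric(2 * flat), 2 * confocal_peak_metric(flat))
  expect_equal(confocal_peak_metric(flat + 5), confocal_peak_metric(flat) + 5)
})

test_that("the quadratic fit finds, clips and rejects vertices correctly", {
  x <- c(-0.4, -0.2, 0, 0.2, 0.4)
  y <- -(x - 0.13)^2 + 2
  qp <- quadratic_peak(x, y)
  expect_equal(qp$vertex, 0.13, tolerance = 1e-10)
  expect_true(qp$corrected)
  # symmetric values: vertex at zero
  expect_equal(quadratic_peak(x, -(x)^2 + 1)$vertex, 0, tolerance = 1e-12)
  # vertex outside the trial range is clipped and flagged
  yc <- -(x - 1.5)^2
  qc <- quadratic_peak(x, yc)
  expect_equal(qc$vertex, 0.4)
  expect_true(qc$clipped)
  # positive curvature: not corrected
  qn <- quadratic_peak(x, x^2)
  expect_false(qn$corrected)
  expect_equal(qn$vertex, 0)
  expect_error(quadratic_peak(c(0, 1), c(1, 2)), ">= 3")
  expect_error(quadratic_peak(c(0, 0, 0), c(1, 2, 3)), "distinct")
})

test_that("one iteration over 5 modes and 5 strengths costs 25 acquisitions", {
  calls <- 0
  imager <- function(cf) {
    calls <<- calls + 1
    matrix(stats::dnorm(seq(-3, 3, length.out = 32)) %o%
             stats::dnorm(seq(-3, 3, length.out = 32)), 32)
  }
  res <- modal_correction_loop(imager,
                               trial_schedule(n_points = 5, n_iterations = 1),
                               metric = function(im) max(im))
  expect_equal(res$n_acquisitions, 25)
  expect_equal(calls, 25)
  expect_equal(nrow(res$history), 25)
})

test_that("the loop recovers no correction for an unaberrated sample", {
  cfg <- small_config(48, 5)
  ph <- make_phantom("beads", cfg, n = 2, min_sep_nm = 800, seed = 9)
  mcfg <- metric_config(cfg)
  imager <- function(cf) simulate_widefield(ph, cf, cfg)[, , 3]
  res <- modal_correction_loop(imager, trial_schedule(n_iterations = 1),
                               function(im) image_quality_metric(im, mcfg))
  expect_lt(max(abs(coeffs_dense(res$coeffs, 15))), 0.02)
})

test_that("ROI-targeted correction maximizes the ROI metric", {
  cfg <- small_config(48, 5)
  ph <- make_phantom("beads", cfg, n = 2, min_sep_nm = 800, seed = 9)
  mcfg <- metric_config(cfg)
  roi <- c(1, 24, 1, 48)
  seen <- list()
  imager <- function(cf) simulate_widefield(ph, cf, cfg)[, , 3]
  res <- modal_correction_loop(
    imager, trial_schedule(modes = 5, n_iterations = 1, roi = roi),
    function(im) {
      seen[[length(seen) + 1]] <<- dim(im)
      image_quality_metric(im, mcfg)
    })
  # the metric only ever saw the ROI
  expect_true(all(vapply(seen, function(d) all(d == c(24, 48)), logical(1))))
})
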