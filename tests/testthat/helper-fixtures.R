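# Shared small-scale fixtures. Heavy objects are built once per test run.

small_config <- function(grid = 64, nz = 9) optical_config(grid_xy = grid, n_z = nz)

# memoized flat PSF on the 64/9 grid
flat_psf_64 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- compute_psf3d(zernike_coeffs(), small_config())
    cache
  }
})

# a pattern whose fundamental fits an integer number of cycles in the field,
# so discrete spectra have exact peaks
commensurate_pattern <- function(config, cycles = 10, ...) {
  si_pattern(period_nm = config$grid_xy * config$pixel_xy / cycles, ...)
}

# half-max width (linear interpolation) of the profile through the volume
# maximum; model-free counterpart of the Gaussian-fit estimator
half_max_width <- function(v, spacing, axis = c("x", "z")) {
  axis <- match.arg(axis)
  pk <- which(v == max(v), arr.ind = TRUE)[1, ]
  pr <- if (axis == "x") v[pk[1], , pk[3]] else v[pk[1], pk[2], ]
  hm <- max(pr) / 2
  ab <- range(which(pr >= hm))
  lo <- stats::approx(pr[c(ab[1] - 1, ab[1])], c(ab[1] - 1, ab[1]), xout = hm)$y
  hi <- stats::approx(pr[c(ab[2], ab[2] + 1)], c(ab[2], ab[2] + 1), xout = hm)$y
  (hi - lo) * spacing
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
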