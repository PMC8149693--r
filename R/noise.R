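#' Camera noise model
#'
#' Poisson shot noise plus Gaussian read noise: a noiseless image `img` in
#' arbitrary density units is scaled to expected photons
#' `photons_per_unit * img + background` and then sampled as
#' `Poisson(expected) + N(0, read_noise_e)`. A `NULL` model (or
#' `photons_per_unit = 0`... all components zero) leaves images noiseless.
#'
#' @param photons_per_unit Photons per unit of simulated density.
#' @param read_noise_e Gaussian read-noise standard deviation (electrons).
#' @param background Constant background level, photons.
#' @param seed Integer seed; identical seeds reproduce identical noise.
#' @return A `noise_model` object.
#' @export
noise_model <- function(photons_per_unit = 200, read_noise_e = 2,
                        background = 5, seed = 1L) {
  stopifnot(photons_per_unit >= 0, read_noise_e >= 0, background >= 0)
  structure(list(photons_per_unit = photons_per_unit,
                 read_noise_e = read_noise_e,
                 background = background, seed = as.integer(seed)),
            class = "noise_model")
}

# Apply a noise model to an array of expected densities. Values are clipped
# at zero after read noise (camera outputs are nonnegative counts).
apply_noise <- function(img, noise = NULL) {
  if (is.null(noise)) return(img)
  stopifnot(inherits(noise, "noise_model"))
  lam <- noise$photons_per_unit * pmax(img, 0) + noise$background
  with_seed(noise$seed, {
    out <- stats::rpois(length(lam), lam)
    if (noise$read_noise_e > 0) {
      out <- out + stats::rnorm(length(lam), 0, noise$read_noise_e)
    }
    array(pmax(out, 0), dim(img))
  })
}
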