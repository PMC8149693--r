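# FFT conventions used throughout:
#  * arrays are stored in "natural" (centered, image-like) layout with the
#    origin at index floor(n/2)+1 along each axis;
#  * spectra are stored in unshifted FFT layout (DC at index [1,1,...]) and
#    frequency axes follow fft_freq();
#  * convolution kernels are ifftshift()ed before transforming so that a
#    kernel centered in the array acts as a centered impulse response.

#' Discrete Fourier-transform sample frequencies
#'
#' Frequencies (cycles per unit of `d`) for an `n`-point FFT in unshifted
#' order: `0, 1/(n d), ..., -1/(n d)`.
#'
#' @param n Number of samples.
#' @param d Sample spacing (e.g. nm per pixel).
#' @return Numeric vector of length `n`.
#' @keywords internal
fft_freq <- function(n, d = 1) {
  stopifnot(n >= 1, d > 0)
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-ceiling((n - 1) / 2), -1L))
  k / (n * d)
}

#' @keywords internal
fft_shift_vec <- function(x, inverse = FALSE) {
  n <- length(x)
  h <- if (inverse) ceiling(n / 2) else floor(n / 2)
  if (h == 0) return(x)
  c(x[(h + 1):n], x[1:h])
}

shift_idx <- function(n, inverse = FALSE) {
  h <- if (inverse) ceiling(n / 2) else floor(n / 2)
  if (h == 0) return(seq_len(n))
  c((h + 1):n, seq_len(h))
}

#' Centre/uncentre the zero frequency of an array
#'
#' `fftshift()` moves the zero frequency from index 1 to the array centre;
#' `ifftshift()` is its exact inverse (they differ for odd sizes).
#'
#' @param x Vector, matrix or 3-D array.
#' @return Array of the same shape.
#' @keywords internal
fftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) return(fft_shift_vec(x))
  idx <- lapply(d, shift_idx)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' @rdname fftshift
#' @keywords internal
ifftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) return(fft_shift_vec(x, inverse = TRUE))
  idx <- lapply(d, shift_idx, inverse = TRUE)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

ifft <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Circular convolution of an array with a centered real/complex kernel.
conv_fft <- function(x, kernel_centered) {
  stopifnot(all(dim(x) == dim(kernel_centered)))
  ifft(stats::fft(x) * stats::fft(ifftshift(kernel_centered)))
}

# Run code with a temporary RNG state seeded by `seed`; restores the caller's
# stream afterwards so simulator seeding never perturbs user code.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Embed a small unshifted 3-D spectrum into a larger lateral grid (Fourier
# zero-padding, i.e. band-limited upsampling by ratio big/small per axis).
embed_spectrum <- function(spec_small, dim_big) {
  ds <- dim(spec_small)
  stopifnot(length(ds) == length(dim_big), all(dim_big >= ds))
  sc <- fftshift(spec_small)
  out <- array(0 + 0i, dim_big)
  off <- floor(dim_big / 2) - floor(ds / 2)
  idx <- lapply(seq_along(ds), function(i) off[i] + seq_len(ds[i]))
  out <- do.call(`[<-`, c(list(out), idx, list(value = sc)))
  ifftshift(out) * prod(dim_big) / prod(ds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
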