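#' Tukey (tapered cosine) window
#'
#' @param n Length.
#' @param gamma Total taper fraction (0 = rectangular, 1 = Hann).
#' @return Numeric vector: 1 on the central plateau, cosine-tapered to 0 at
#'   both ends.
#' @export
tukey_window <- function(n, gamma = 0.08) {
  stopifnot(n >= 1, gamma >= 0, gamma <= 1)
  if (gamma == 0) return(rep(1, n))
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < gamma / 2
  hi <- x > 1 - gamma / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / gamma - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (x[hi] - 1) / gamma + 1)))
  w
}

tukey_volume <- function(dims, gamma) {
  wy <- tukey_window(dims[1], gamma)
  wx <- tukey_window(dims[2], gamma)
  wz <- tukey_window(dims[3], gamma)
  outer(outer(wy, wx), wz)
}

#' Separate the frequency orders of a raw SIM stack
#'
#' Per orientation, inverts the 5 x 5 phase-mixing matrix
#' `M[phi, m] = exp(i m phi)` applied to the 3-D Fourier transforms of the
#' five phase-stepped frames, recovering the order components
#' `D_{j,m}(k)` for m = -2..2. For equally spaced phases the matrix is
#' unitary up to scale and the inversion is exact; otherwise a pseudo-inverse
#' is used with a warning.
#'
#' A real-space Tukey window (the spectral convolution in the reconstruction
#' formula) is applied to each frame before transforming to suppress FFT
#' edge discontinuities; set `tukey_gamma = 0` to disable.
#'
#' @param stack A [simulate_sim_stack] / [read_raw_stack] result.
#' @param tukey_gamma Taper fraction of the 3-D Tukey window.
#' @return A `separated_orders` object: `components[[j]][[as.character(m)]]`
#'   complex arrays in unshifted FFT layout, plus pattern/config metadata.
#' @export
separate_orders <- function(stack, tukey_gamma = 0.08) {
  stopifnot(inherits(stack, "sim_stack") || is.list(stack))
  dat <- stack$data
  d <- dim(dat)
  n_ph <- d[4]; n_or <- d[5]
  phases <- stack$pattern$phases_rad
  stopifnot(length(phases) == n_ph)
  ms <- -((n_ph - 1) %/% 2):((n_ph) %/% 2)  # -2..2 for 5 phases
  M <- outer(phases, ms, function(p, m) exp(1i * m * p))
  dphi <- diff(sort(phases %% (2 * pi)))
  equal <- (max(dphi) - min(dphi)) < 1e-6
  Minv <- if (equal) {
    solve(M)
  } else {
    warning("phases are not equally spaced; using pseudo-inverse", call. = FALSE)
    sv <- svd(M)
    sv$v %*% diag(1 / sv$d) %*% Conj(t(sv$u))
  }
  win <- if (tukey_gamma > 0) tukey_volume(d[1:3], tukey_gamma) else NULL
  comps <- vector("list", n_or)
  for (j in seq_len(n_or)) {
    ft <- vector("list", n_ph)
    for (p in seq_len(n_ph)) {
      fr <- dat[, , , p, j, drop = FALSE][, , , 1, 1]
      if (!is.null(win)) fr <- fr * win
      ft[[p]] <- stats::fft(fr)
    }
    cj <- vector("list", length(ms))
    names(cj) <- as.character(ms)
    for (im in seq_along(ms)) {
      acc <- array(0 + 0i, d[1:3])
      for (p in seq_len(n_ph)) acc <- acc + Minv[im, p] * ft[[p]]
      cj[[im]] <- acc
    }
    comps[[j]] <- cj
  }
  structure(list(components = comps, orders = ms,
                 pattern = stack$pattern, config = stack$config,
                 tukey_gamma = tukey_gamma),
            class = "separated_orders")
}

#' @export
print.separated_orders <- function(x, ...) {
  cat(sprintf("<separated_orders> %d orientations, orders %s, grid %s\n",
              length(x$components), paste(x$orders, collapse = ","),
              paste(dim(x$components[[1]][[1]]), collapse = "x")))
  invisible(x)
}

# Forward phase mixing: builds the 5-phase frames of one orientation from
# known complex order components (test oracle for separate_orders).
mix_orders <- function(components, phases) {
  ms <- as.integer(names(components))
  d <- dim(components[[1]])
  out <- array(0, c(d, length(phases)))
  for (p in seq_along(phases)) {
    acc <- array(0 + 0i, d)
    for (im in seq_along(ms)) {
      acc <- acc + exp(1i * ms[im] * phases[p]) * components[[im]]
    }
    out[, , , p] <- Re(acc)
  }
  out
}
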