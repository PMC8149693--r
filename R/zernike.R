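#' Zernike mode coefficient sets
#'
#' A `zernike_coeffs` object maps Noll mode indices to modal amplitudes in
#' micrometres of optical path difference. Amplitudes are coefficients of
#' Noll-normalized modes (unit RMS over the pupil for every mode), so an
#' amplitude is directly an RMS wavefront contribution.
#'
#' Two indexing conventions are supported: `"noll_1based"` (Noll's original
#' convention: 1 = piston, 4 = defocus, 5/6 = astigmatism, 7/8 = coma,
#' 11 = primary spherical) and `"paper_0based"`, a zero-based relabelling in
#' which mode `k` means Noll `k + 1` (so 4, 5, 6, 7 and 10 are astigmatism,
#' oblique astigmatism, both comas and spherical). Objects are normalized to
#' `noll_1based` on construction.
#'
#' @param amplitudes Named numeric vector; names are mode indices.
#' @param indexing `"noll_1based"` (default) or `"paper_0based"`.
#' @return A `zernike_coeffs` object (named numeric vector, 1-based Noll).
#' @examples
#' zernike_coeffs(c(`5` = 0.2))                      # 0.2 um oblique astigmatism
#' zernike_coeffs(c(`4` = 0.2), "paper_0based")      # same mode, 0-based label
#' @export
zernike_coeffs <- function(amplitudes = numeric(0),
                           indexing = c("noll_1based", "paper_0based")) {
  indexing <- match.arg(indexing)
  if (length(amplitudes) == 0) {
    out <- numeric(0)
    attr(out, "indices") <- integer(0)
    class(out) <- "zernike_coeffs"
    return(out)
  }
  if (is.null(names(amplitudes))) {
    stop("`amplitudes` must be named by mode index", call. = FALSE)
  }
  idx <- as.integer(names(amplitudes))
  if (anyNA(idx) || !all(is.finite(amplitudes))) {
    stop("mode indices must be integers and amplitudes finite", call. = FALSE)
  }
  if (indexing == "paper_0based") idx <- idx + 1L
  if (any(idx < 1L)) stop("Noll indices must be >= 1", call. = FALSE)
  amp <- as.numeric(amplitudes)
  o <- order(idx)
  idx <- idx[o]; amp <- amp[o]
  if (anyDuplicated(idx)) {
    amp <- as.numeric(tapply(amp, idx, sum))
    idx <- sort(unique(idx))
  }
  out <- amp
  names(out) <- as.character(idx)
  attr(out, "indices") <- idx
  class(out) <- "zernike_coeffs"
  out
}

#' @export
print.zernike_coeffs <- function(x, ...) {
  if (length(x) == 0) {
    cat("<zernike_coeffs> (flat)\n")
    return(invisible(x))
  }
  nm <- noll_to_nm(attr(x, "indices"))
  cat("<zernike_coeffs> (um, Noll-normalized modes)\n")
  print(tidy.zernike_coeffs(x), ...)
  invisible(x)
}

#' Tidy a Zernike coefficient set
#'
#' @param x A `zernike_coeffs` object.
#' @param ... Unused.
#' @return Tibble with columns `noll`, `n`, `m`, `amplitude_um`.
#' @export
tidy.zernike_coeffs <- function(x, ...) {
  idx <- attr(x, "indices") %||% integer(0)
  nm <- noll_to_nm(idx)
  tibble::tibble(
    noll = idx,
    n = nm$n,
    m = nm$m,
    amplitude_um = as.numeric(x)
  )
}

# Coefficient vector over modes 1..n_max (dense), for arithmetic.
coeffs_dense <- function(coeffs, n_max = NULL) {
  idx <- attr(coeffs, "indices") %||% integer(0)
  n_max <- n_max %||% if (length(idx)) max(idx) else 0L
  v <- numeric(n_max)
  if (length(idx)) v[idx] <- as.numeric(coeffs)
  v
}

coeffs_from_dense <- function(v, drop_tol = 0) {
  keep <- which(abs(v) > drop_tol)
  zernike_coeffs(stats::setNames(v[keep], as.character(keep)))
}

#' Convert Noll indices to radial/azimuthal orders
#'
#' @param j Integer vector of Noll indices (>= 1).
#' @return List with integer vectors `n` (radial order) and `m` (signed
#'   azimuthal frequency; negative means the sine term).
#' @export
noll_to_nm <- function(j) {
  j <- as.integer(j)
  if (any(j < 1L)) stop("Noll indices must be >= 1", call. = FALSE)
  nn <- integer(length(j)); mm <- integer(length(j))
  for (i in seq_along(j)) {
    jj <- j[i]
    n <- 0L; pos <- jj
    while (pos > n + 1L) {
      pos <- pos - (n + 1L)
      n <- n + 1L
    }
    # |m| sequence within radial order n: even n -> 0,2,2,4,4,...; odd -> 1,1,3,3,...
    am <- if (n %% 2L == 0L) 2L * ((pos %/% 2L)) else 2L * ((pos - 1L) %/% 2L) + 1L
    if (am == 0L) {
      m <- 0L
    } else {
      # Noll: odd j carries the sine term (m < 0), even j the cosine term.
      m <- if (jj %% 2L == 0L) am else -am
    }
    nn[i] <- n; mm[i] <- m
  }
  list(n = nn, m = mm)
}

# Radial polynomial R_n^{|m|}(rho).
zernike_radial <- function(n, m_abs, rho) {
  out <- numeric(length(rho))
  for (k in 0:((n - m_abs) / 2)) {
    cf <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m_abs) / 2 - k) * factorial((n - m_abs) / 2 - k))
    out <- out + cf * rho^(n - 2 * k)
  }
  out
}

#' Evaluate a Noll-normalized Zernike mode at polar coordinates
#'
#' Normalization follows Noll: `sqrt(n+1)` for m = 0 and `sqrt(2(n+1))`
#' otherwise, giving unit RMS over the unit disk.
#'
#' @param j Noll index (>= 1).
#' @param rho Radial coordinate(s), 0..1 inside the pupil.
#' @param theta Azimuth(s), radians.
#' @return Numeric vector/array shaped like `rho`.
#' @export
zernike_eval <- function(j, rho, theta) {
  stopifnot(length(j) == 1, j >= 1)
  nm <- noll_to_nm(j)
  n <- nm$n; m <- nm$m; am <- abs(m)
  rad <- zernike_radial(n, am, rho)
  val <- if (m == 0L) {
    sqrt(n + 1) * rad
  } else if (m > 0L) {
    sqrt(2 * (n + 1)) * rad * cos(am * theta)
  } else {
    sqrt(2 * (n + 1)) * rad * sin(am * theta)
  }
  dim(val) <- dim(rho)
  val
}

unit_disk_grid <- function(grid_size) {
  x <- seq(-1, 1, length.out = grid_size)
  xx <- matrix(x, grid_size, grid_size, byrow = TRUE)   # column coordinate
  yy <- matrix(x, grid_size, grid_size)                 # row coordinate
  rho <- sqrt(xx^2 + yy^2)
  list(x = xx, y = yy, rho = rho, theta = atan2(yy, xx), mask = rho <= 1)
}

#' Sample a single Zernike mode on a square pupil grid
#'
#' @param index Noll index (>= 1).
#' @param grid_size Samples per side (>= 16); the pupil is the inscribed disk.
#' @return A [wavefront] with unit-amplitude modal phase (um per um of
#'   coefficient) inside the pupil and zero outside.
#' @examples
#' w <- zernike_mode(4, 64)      # defocus, sqrt(3)(2 r^2 - 1)
#' @export
zernike_mode <- function(index, grid_size) {
  if (length(index) != 1 || !is.finite(index) || index < 1) {
    stop("`index` must be a positive Noll index", call. = FALSE)
  }
  if (length(grid_size) != 1 || !is.finite(grid_size) || grid_size < 16) {
    stop("`grid_size` must be an integer >= 16", call. = FALSE)
  }
  g <- unit_disk_grid(grid_size)
  ph <- zernike_eval(as.integer(index), g$rho, g$theta)
  ph[!g$mask] <- 0
  wavefront(ph, g$mask)
}

#' Combine Zernike coefficients into a sampled wavefront
#'
#' The phase map is the linear combination `sum_j c_j Z_j` over the unit
#' disk, in micrometres of optical path difference.
#'
#' @param coeffs A [zernike_coeffs] object (or named vector accepted by it).
#' @param grid_size Samples per side.
#' @return A [wavefront].
#' @export
synthesize_wavefront <- function(coeffs, grid_size) {
  if (!inherits(coeffs, "zernike_coeffs")) coeffs <- zernike_coeffs(coeffs)
  g <- unit_disk_grid(grid_size)
  ph <- matrix(0, grid_size, grid_size)
  idx <- attr(coeffs, "indices")
  for (i in seq_along(idx)) {
    ph <- ph + as.numeric(coeffs)[i] * zernike_eval(idx[i], g$rho, g$theta)
  }
  ph[!g$mask] <- 0
  wavefront(ph, g$mask)
}
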