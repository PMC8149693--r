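#' Shack-Hartmann sensor geometry
#'
#' Lenslet-array geometry of the direct wavefront sensor. The conjugated
#' pupil (default 2.27 mm across) covers about 14 lenslets of 146 um pitch;
#' the maximum measurable phase step per lenslet is `d^2 / (2 f_ML)`.
#'
#' @param lenslet_pitch_um Lenslet diameter/pitch d, um.
#' @param lenslet_focal_mm Lenslet focal length f_ML, mm.
#' @param pupil_diameter_mm Conjugated pupil diameter at the array, mm.
#' @param lenslets_across Lenslets across the sampled square.
#' @param sensor_pixel_um Camera pixel at the lenslet focal plane, um.
#' @param window_px Pixels per lenslet sub-window on the camera.
#' @param spot_sigma_px Rendered spot Gaussian sigma, px (diffraction-scale).
#' @return An `sh_geometry`.
#' @export
sh_geometry <- function(lenslet_pitch_um = 146, lenslet_focal_mm = 5.2,
                        pupil_diameter_mm = 2.27, lenslets_across = 14,
                        sensor_pixel_um = 9.125, window_px = 16,
                        spot_sigma_px = 1.2) {
  stopifnot(lenslet_pitch_um > 0, lenslet_focal_mm > 0,
            pupil_diameter_mm > 0, lenslets_across >= 4)
  structure(list(lenslet_pitch_um = lenslet_pitch_um,
                 lenslet_focal_mm = lenslet_focal_mm,
                 pupil_diameter_mm = pupil_diameter_mm,
                 lenslets_across = as.integer(lenslets_across),
                 sensor_pixel_um = sensor_pixel_um,
                 window_px = as.integer(window_px),
                 spot_sigma_px = spot_sigma_px),
            class = "sh_geometry")
}

#' Maximum measurable wavefront excursion of the sensor
#'
#' Geometric dynamic range `d^2 / (2 f_ML)`: the phase change across one
#' lenslet that displaces its spot by half a pitch.
#'
#' @param geometry An [sh_geometry].
#' @return Micrometres.
#' @examples
#' max_measurable_phase(sh_geometry())   # 2.05 um
#' @export
max_measurable_phase <- function(geometry) {
  stopifnot(inherits(geometry, "sh_geometry"))
  d_um <- geometry$lenslet_pitch_um
  f_um <- geometry$lenslet_focal_mm * 1000
  d_um^2 / (2 * f_um)
}

# Lenslet centre coordinates: lattice of pitch d centred on the pupil,
# in um at the lenslet plane and normalized pupil units.
lenslet_centers <- function(geometry) {
  L <- geometry$lenslets_across
  d <- geometry$lenslet_pitch_um
  r_pupil <- geometry$pupil_diameter_mm * 1000 / 2
  pos <- (seq_len(L) - (L + 1) / 2) * d
  cx <- matrix(pos, L, L, byrow = TRUE)
  cy <- matrix(pos, L, L)
  rr <- sqrt(cx^2 + cy^2)
  in_pupil <- (rr + d / 2) <= r_pupil * 1.02  # lenslet fully (almost) inside
  list(cx_um = cx, cy_um = cy, x_norm = cx / r_pupil, y_norm = cy / r_pupil,
       in_pupil = in_pupil, r_pupil_um = r_pupil)
}

# Mean wavefront gradient (um OPD per um at the lenslet plane) over each
# lenslet footprint, from a wavefront sampled on the pupil square.
lenslet_slopes <- function(wf, geometry) {
  lc <- lenslet_centers(geometry)
  n <- wf$grid_size
  # wavefront grid spans the pupil diameter: sample spacing in um
  h_um <- (2 * lc$r_pupil_um) / (n - 1)
  gx <- matrix(NA_real_, n, n); gy <- matrix(NA_real_, n, n)
  ph <- wf$phase
  ph[!wf$mask] <- NA  # no light outside the pupil; do not difference across it
  gx[, 2:(n - 1)] <- (ph[, 3:n] - ph[, 1:(n - 2)]) / (2 * h_um)
  gy[2:(n - 1), ] <- (ph[3:n, ] - ph[1:(n - 2), ]) / (2 * h_um)
  xs <- seq(-lc$r_pupil_um, lc$r_pupil_um, length.out = n)
  L <- geometry$lenslets_across
  d <- geometry$lenslet_pitch_um
  sx <- matrix(NA_real_, L, L); sy <- matrix(NA_real_, L, L)
  g <- unit_disk_grid(n)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (!lc$in_pupil[i, j]) next
    ii <- which(abs(xs - lc$cy_um[i, j]) <= d / 2)
    jj <- which(abs(xs - lc$cx_um[i, j]) <= d / 2)
    sub_mask <- g$mask[ii, jj]
    if (mean(sub_mask) < 0.5) next
    sx[i, j] <- mean(gx[ii, jj][sub_mask], na.rm = TRUE)
    sy[i, j] <- mean(gy[ii, jj][sub_mask], na.rm = TRUE)
  }
  list(sx = sx, sy = sy, valid = lc$in_pupil & is.finite(sx) & is.finite(sy))
}

#' Simulate a Shack-Hartmann frame
#'
#' Each lenslet's focal spot is displaced by `f_ML` times the mean local
#' wavefront gradient over the lenslet and rendered as a diffraction-scale
#' Gaussian spot in its camera sub-window. Lenslets whose spot displacement
#' exceeds half the pitch (gradient beyond the `d^2/(2 f_ML)` dynamic
#' range) are flagged saturated and produce no detectable spot.
#'
#' @param wf A [wavefront] sampled over the pupil square (OPD in um).
#' @param geometry An [sh_geometry].
#' @param star_intensity Peak photon scale of each spot.
#' @param noise A [noise_model] or `NULL`.
#' @return An `sh_frame`: `image`, per-lenslet `valid_mask` and `saturated`
#'   matrices, true displacements (simulation metadata) and the geometry.
#' @export
simulate_shwfs_frame <- function(wf, geometry = sh_geometry(),
                                 star_intensity = 1000, noise = NULL) {
  stopifnot(inherits(wf, "wavefront"), inherits(geometry, "sh_geometry"))
  sl <- lenslet_slopes(wf, geometry)
  f_um <- geometry$lenslet_focal_mm * 1000
  disp_x_um <- f_um * sl$sx
  disp_y_um <- f_um * sl$sy
  d <- geometry$lenslet_pitch_um
  sat <- is.finite(disp_x_um) & (pmax(abs(disp_x_um), abs(disp_y_um)) > d / 2)
  valid <- sl$valid & !sat
  L <- geometry$lenslets_across; wpx <- geometry$window_px
  img <- matrix(0, L * wpx, L * wpx)
  ctr <- (wpx + 1) / 2
  pxum <- geometry$sensor_pixel_um
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (!isTRUE(valid[i, j])) next
    x0 <- ctr + disp_x_um[i, j] / pxum
    y0 <- ctr + disp_y_um[i, j] / pxum
    gx <- exp(-((seq_len(wpx) - x0)^2) / (2 * geometry$spot_sigma_px^2))
    gy <- exp(-((seq_len(wpx) - y0)^2) / (2 * geometry$spot_sigma_px^2))
    sp <- star_intensity * outer(gy, gx)
    img[(i - 1) * wpx + seq_len(wpx), (j - 1) * wpx + seq_len(wpx)] <- sp
  }
  img <- apply_noise(img, noise)
  structure(list(image = img, geometry = geometry, valid_mask = valid,
                 saturated = sat,
                 true_disp_x_um = disp_x_um, true_disp_y_um = disp_y_um),
            class = "sh_frame")
}

#' @export
print.sh_frame <- function(x, ...) {
  cat(sprintf("<sh_frame> %d x %d px, %d/%d valid lenslets (%d saturated)\n",
              nrow(x$image), ncol(x$image), sum(x$valid_mask, na.rm = TRUE),
              x$geometry$lenslets_across^2, sum(x$saturated, na.rm = TRUE)))
  invisible(x)
}

# FFT cross-correlation of one sub-window pair with parabolic 3x3 sub-pixel
# peak interpolation; returns the (dx, dy) displacement in pixels.
window_xcorr <- function(win, ref) {
  w1 <- win - mean(win); r1 <- ref - mean(ref)
  cc <- Re(ifft(stats::fft(w1) * Conj(stats::fft(r1))))
  pk <- unname(which(cc == max(cc), arr.ind = TRUE)[1, ])
  n <- nrow(cc)
  sub <- function(mat, i, j) mat[(i - 1) %% n + 1, (j - 1) %% n + 1]
  # Gaussian (log-parabolic) peak interpolation: exact for Gaussian spots,
  # avoiding the pixel-locking bias of a plain parabola
  para <- function(m1, m0, p1) {
    if (m1 <= 0 || p1 <= 0 || m0 <= 0) {
      den <- m1 - 2 * m0 + p1
      return(if (den >= 0) 0 else 0.5 * (m1 - p1) / den)
    }
    l1 <- log(m1); l0 <- log(m0); lp <- log(p1)
    den <- l1 - 2 * l0 + lp
    if (den >= 0) 0 else 0.5 * (l1 - lp) / den
  }
  di <- para(sub(cc, pk[1] - 1, pk[2]), cc[pk[1], pk[2]], sub(cc, pk[1] + 1, pk[2]))
  dj <- para(sub(cc, pk[1], pk[2] - 1), cc[pk[1], pk[2]], sub(cc, pk[1], pk[2] + 1))
  dy <- pk[1] - 1 + di; dx <- pk[2] - 1 + dj
  if (dy > n / 2) dy <- dy - n
  if (dx > n / 2) dx <- dx - n
  c(dx = dx, dy = dy)
}

#' Per-lenslet wavefront gradients from spot displacements
#'
#' Cross-correlates each lenslet sub-window against the aberration-free
#' reference frame; the sub-pixel correlation peak gives the spot
#' displacement and hence the local wavefront slope
#' `displacement / f_ML` (dimensionless, um OPD per um). Lenslets without a
#' detectable spot (intensity below `min_peak_frac` of the reference spot)
#' are marked invalid.
#'
#' @param frame,reference [simulate_shwfs_frame] results (same geometry).
#' @param min_peak_frac Detection threshold relative to the reference spot
#'   peak.
#' @return Tibble with one row per lenslet: indices, normalized pupil
#'   coordinates, displacements (px), slopes, and `valid`.
#' @export
spot_gradients <- function(frame, reference, min_peak_frac = 0.2) {
  stopifnot(inherits(frame, "sh_frame"), inherits(reference, "sh_frame"))
  geo <- frame$geometry
  stopifnot(identical(geo$lenslets_across, reference$geometry$lenslets_across),
            identical(geo$window_px, reference$geometry$window_px))
  L <- geo$lenslets_across; wpx <- geo$window_px
  f_um <- geo$lenslet_focal_mm * 1000
  lc <- lenslet_centers(geo)
  ref_peak <- max(reference$image)
  rows <- vector("list", L * L)
  k <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    k <- k + 1
    ii <- (i - 1) * wpx + seq_len(wpx); jj <- (j - 1) * wpx + seq_len(wpx)
    win <- frame$image[ii, jj]; ref <- reference$image[ii, jj]
    ok <- isTRUE(reference$valid_mask[i, j]) &&
      max(win) >= min_peak_frac * ref_peak && max(ref) > 0
    if (ok) {
      dd <- window_xcorr(win, ref)
      sx <- dd[["dx"]] * geo$sensor_pixel_um / f_um
      sy <- dd[["dy"]] * geo$sensor_pixel_um / f_um
    } else {
      dd <- c(dx = NA_real_, dy = NA_real_); sx <- NA_real_; sy <- NA_real_
    }
    rows[[k]] <- tibble::tibble(
      i = i, j = j, x_norm = lc$x_norm[i, j], y_norm = lc$y_norm[i, j],
      dx_px = dd[["dx"]], dy_px = dd[["dy"]],
      slope_x = sx, slope_y = sy, valid = ok)
  }
  dplyr::bind_rows(rows)
}

# Fill NA entries of a matrix by iterative 4-neighbour averaging (only used
# for the few invalid lenslets inside the pupil).
inpaint_nn <- function(m, within) {
  for (it in 1:50) {
    nas <- which(is.na(m) & within, arr.ind = TRUE)
    if (!nrow(nas)) break
    for (r in seq_len(nrow(nas))) {
      i <- nas[r, 1]; j <- nas[r, 2]
      nb <- c(if (i > 1) m[i - 1, j], if (i < nrow(m)) m[i + 1, j],
              if (j > 1) m[i, j - 1], if (j < ncol(m)) m[i, j + 1])
      nb <- nb[is.finite(nb)]
      if (length(nb)) m[i, j] <- mean(nb)
    }
  }
  m[is.na(m)] <- 0
  m
}

#' Fourier-transform wavefront reconstruction from slopes
#'
#' Least-squares integration of the two slope fields in the Fourier domain:
#' the wavefront spectrum is `(-i kx Sx - i ky Sy) / (2 pi (kx^2 + ky^2))`
#' with the zero frequency set to 0. Boundary and coarse-sampling bias are
#' controlled by (i) spline-upsampling the slope fields before integration,
#' (ii) an even mirror extension replacing the periodic boundary
#' assumption, and (iii) a few residual-correction iterations confined to
#' the pupil, which make the integrated surface's spectral gradient match
#' the measured slopes. Invalid lenslets (at least 70% must be valid inside
#' the pupil) are inpainted from their neighbours. The result is mean-free
#' over the pupil.
#'
#' @param gradients Tibble from [spot_gradients] (or a list with matrices
#'   `sx`, `sy`, `valid`).
#' @param geometry An [sh_geometry].
#' @param upsample Spline-upsampling factor of the slope grid.
#' @param n_iter Residual-correction iterations.
#' @return A [wavefront] on the lenslet grid (um), with normalized pupil
#'   coordinates attached.
#' @export
ft_reconstruct_wavefront <- function(gradients, geometry = sh_geometry(),
                                     upsample = 4, n_iter = 8) {
  L <- geometry$lenslets_across
  if (is.data.frame(gradients)) {
    sx <- matrix(NA_real_, L, L); sy <- matrix(NA_real_, L, L)
    valid <- matrix(FALSE, L, L)
    idx <- cbind(gradients$i, gradients$j)
    sx[idx] <- gradients$slope_x
    sy[idx] <- gradients$slope_y
    valid[idx] <- gradients$valid
  } else {
    sx <- gradients$sx; sy <- gradients$sy; valid <- gradients$valid
  }
  valid[!is.finite(sx) | !is.finite(sy)] <- FALSE
  lc <- lenslet_centers(geometry)
  n_in <- sum(lc$in_pupil)
  if (sum(valid & lc$in_pupil) < 0.7 * n_in) {
    stop(sprintf("only %d/%d lenslets valid inside the pupil (need >= 70%%)",
                 sum(valid & lc$in_pupil), n_in), call. = FALSE)
  }
  sx[!valid] <- NA; sy[!valid] <- NA
  sx <- inpaint_nn(sx, lc$in_pupil)
  sy <- inpaint_nn(sy, lc$in_pupil)
  d_um <- geometry$lenslet_pitch_um
  # each lenslet reports the mean gradient over its d x d footprint, i.e.
  # the true gradient box-smoothed: s_meas ~ s + (d^2/24) lap(s). Undo the
  # leading-order bias with a discrete Laplacian (replicated edges)
  unbox <- function(s) {
    se <- rbind(s[1, ], s, s[L, ])
    se <- cbind(se[, 1], se, se[, L])
    lap <- (se[1:L, 2:(L + 1)] + se[3:(L + 2), 2:(L + 1)] +
              se[2:(L + 1), 1:L] + se[2:(L + 1), 3:(L + 2)] - 4 * s) / d_um^2
    s - d_um^2 / 24 * lap
  }
  sx <- unbox(sx); sy <- unbox(sy)
  u <- as.integer(upsample)
  # fine grid through the lenslet centres (spacing d/u)
  nf <- u * (L - 1) + 1
  up2d <- function(m) {
    # apply(X, 1, f) stacks f(X[r, ]) as columns, so two passes upsample
    # columns then rows without an extra transpose
    t1 <- apply(m, 1, function(r) stats::spline(seq_len(L), r, n = nf)$y)
    apply(t1, 1, function(r) stats::spline(seq_len(L), r, n = nf)$y)
  }
  sxf <- up2d(sx); syf <- up2d(sy)
  hf <- d_um / u
  pos_f <- (seq_len(nf) - (nf + 1) / 2) * hf
  rr_f <- sqrt(outer(pos_f^2, pos_f^2, `+`))
  in_pupil_f <- rr_f <= lc$r_pupil_um
  n2 <- 2 * nf
  kx <- fft_freq(n2, hf)
  KX <- matrix(kx, n2, n2, byrow = TRUE); KY <- matrix(kx, n2, n2)
  K2 <- KX^2 + KY^2
  mirror_even <- function(W) {
    M <- matrix(0, n2, n2)
    M[1:nf, 1:nf] <- W
    M[1:nf, (nf + 1):n2] <- W[, nf:1]
    M[(nf + 1):n2, 1:nf] <- W[nf:1, ]
    M[(nf + 1):n2, (nf + 1):n2] <- W[nf:1, nf:1]
    M
  }
  integrate_once <- function(gx, gy) {
    SX <- matrix(0, n2, n2); SY <- matrix(0, n2, n2)
    SX[1:nf, 1:nf] <- gx; SY[1:nf, 1:nf] <- gy
    SX[1:nf, (nf + 1):n2] <- -gx[, nf:1]; SY[1:nf, (nf + 1):n2] <- gy[, nf:1]
    SX[(nf + 1):n2, 1:nf] <- gx[nf:1, ]; SY[(nf + 1):n2, 1:nf] <- -gy[nf:1, ]
    SX[(nf + 1):n2, (nf + 1):n2] <- -gx[nf:1, nf:1]
    SY[(nf + 1):n2, (nf + 1):n2] <- -gy[nf:1, nf:1]
    FW <- (-1i * KX * stats::fft(SX) - 1i * KY * stats::fft(SY)) / (2 * pi * K2)
    FW[1, 1] <- 0
    Re(ifft(FW))[1:nf, 1:nf]
  }
  grad_spec <- function(W) {
    FW <- stats::fft(mirror_even(W))
    list(gx = Re(ifft(2i * pi * KX * FW))[1:nf, 1:nf],
         gy = Re(ifft(2i * pi * KY * FW))[1:nf, 1:nf])
  }
  W <- integrate_once(sxf, syf)
  for (it in seq_len(n_iter)) {
    g <- grad_spec(W)
    W <- W + integrate_once((sxf - g$gx) * in_pupil_f, (syf - g$gy) * in_pupil_f)
  }
  # sample back at the lenslet centres
  ctr_idx <- 1 + u * (seq_len(L) - 1)
  Wc <- W[ctr_idx, ctr_idx]
  Wc[lc$in_pupil] <- Wc[lc$in_pupil] - mean(Wc[lc$in_pupil])
  Wc[!lc$in_pupil] <- 0
  wavefront(Wc, mask = lc$in_pupil,
            coords = list(x = lc$x_norm, y = lc$y_norm))
}

#' Decompose a wavefront into Zernike modes
#'
#' Pixelated Zernike modes are generated at the wavefront's own sampling
#' and orthogonalized by a Gram-Schmidt (QR) procedure to remove the
#' crosstalk that digitization introduces between modes; coefficients are
#' reported in the original Zernike basis by back-substitution through the
#' mixing matrix. This equals a least-squares fit on the pupil mask.
#' `method = "projection"` gives the naive (non-orthogonalized) projection
#' for comparison.
#'
#' @param wf A [wavefront].
#' @param n_modes Number of Noll modes (1..n_modes).
#' @param method `"gram_schmidt"` (default) or `"projection"`.
#' @return A [zernike_coeffs].
#' @export
decompose_to_zernike <- function(wf, n_modes = 15,
                                 method = c("gram_schmidt", "projection")) {
  method <- match.arg(method)
  stopifnot(inherits(wf, "wavefront"))
  keep <- which(wf$mask)
  if (n_modes > length(keep)) {
    stop("`n_modes` exceeds the number of pupil samples", call. = FALSE)
  }
  if (is.null(wf$coords)) {
    g <- unit_disk_grid(wf$grid_size)
    xx <- g$x; yy <- g$y
  } else {
    xx <- wf$coords$x; yy <- wf$coords$y
  }
  rho <- sqrt(xx^2 + yy^2)[keep]
  theta <- atan2(yy, xx)[keep]
  Z <- vapply(seq_len(n_modes),
              function(j) zernike_eval(j, rho, theta), numeric(length(keep)))
  w <- wf$phase[keep]
  cf <- if (method == "gram_schmidt") {
    qrz <- qr(Z)
    backsolve(qr.R(qrz), crossprod(qr.Q(qrz), w))[, 1]
  } else {
    colSums(Z * w) / colSums(Z^2)
  }
  zernike_coeffs(stats::setNames(cf, as.character(seq_len(n_modes))))
}

#' Remove piston, tip, tilt and defocus
#'
#' Zeroes Noll modes 1-4 of a coefficient set: tip/tilt largely reflect the
#' registration offset between the measured and reference spot patterns,
#' and defocus is biased by out-of-focus light, so neither is corrected.
#' Idempotent.
#'
#' @param coeffs A [zernike_coeffs].
#' @return A [zernike_coeffs] with modes 1-4 removed.
#' @export
remove_ptt_defocus <- function(coeffs) {
  if (!inherits(coeffs, "zernike_coeffs")) coeffs <- zernike_coeffs(coeffs)
  v <- coeffs_dense(coeffs)
  if (length(v) >= 1) v[seq_len(min(4, length(v)))] <- 0
  coeffs_from_dense(v)
}
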