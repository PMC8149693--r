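#' Synthetic fluorophore phantoms
#'
#' Generates a nonnegative fluorophore density volume plus ground truth.
#' Three kinds are supported:
#' \describe{
#'   \item{`beads`}{Spheres of the given diameters (nm) at random sub-voxel
#'     positions with a minimum separation; mimics mixed 100/200-nm bead
#'     slides used for resolution calibration.}
#'   \item{`filaments`}{Smooth random tubes (Gaussian cross-section),
#'     loosely mimicking cytoskeletal fibres.}
#'   \item{`shell`}{A spherical shell with density exactly zero strictly
#'     inside the inner radius.}
#' }
#' Bead voxelization is anti-aliased by 5x5x5 subsampling of boundary
#' voxels so the integrated mass matches the analytic sphere volume.
#'
#' @param kind `"beads"`, `"filaments"` or `"shell"`.
#' @param config An [optical_config] giving grid shape and voxel size.
#' @param n Number of beads / filaments.
#' @param diameter_nm Bead diameter(s), nm; recycled over beads.
#' @param min_sep_nm Minimum bead centre separation, nm.
#' @param intensity Density value inside structures.
#' @param margin_frac Fraction of the lateral field kept clear at the edges.
#' @param radius_nm Shell mid-radius (nm); `thickness_nm` its thickness.
#' @param thickness_nm Shell thickness, nm.
#' @param filament_sigma_nm Tube Gaussian radius, nm.
#' @param seed Integer seed; identical seeds give identical phantoms.
#' @return A `phantom` object: `density` array `(y, x, z)`, `kind`, and a
#'   tibble `positions` of ground-truth coordinates (nm, relative to the
#'   volume centre) for beads.
#' @export
make_phantom <- function(kind = c("beads", "filaments", "shell"),
                         config = optical_config(),
                         n = 10, diameter_nm = c(100, 200),
                         min_sep_nm = 1000, intensity = 1,
                         margin_frac = 0.15,
                         radius_nm = NULL, thickness_nm = 300,
                         filament_sigma_nm = 80,
                         seed = NULL) {
  kind <- match.arg(kind)
  nx <- config$grid_xy; nz <- config$n_z
  if (nx <= 0 || nz <= 0) stop("phantom shape must be positive", call. = FALSE)
  dens <- array(0, c(nx, nx, nz))
  positions <- tibble::tibble(x_nm = numeric(0), y_nm = numeric(0),
                              z_nm = numeric(0), diameter_nm = numeric(0))
  px <- config$pixel_xy; zs <- config$z_step

  with_seed(seed, {
    if (kind == "beads") {
      half_xy <- (nx / 2 - nx * margin_frac) * px
      half_z <- max((nz / 2 - 1.5) * zs, 0)
      pts <- matrix(numeric(0), 0, 3)
      tries <- 0
      while (nrow(pts) < n && tries < 200 * n) {
        cand <- c(stats::runif(2, -half_xy, half_xy), stats::runif(1, -half_z, half_z))
        ok <- !nrow(pts) || all(sqrt(rowSums(sweep(pts, 2, cand)^2)) >= min_sep_nm)
        if (ok) pts <- rbind(pts, cand)
        tries <- tries + 1
      }
      if (nrow(pts) < n) stop("could not place beads with the requested separation", call. = FALSE)
      dia <- rep_len(diameter_nm, n)
      for (b in seq_len(n)) {
        dens <- add_bead(dens, pts[b, ], dia[b] / 2, intensity, px, zs)
      }
      positions <- tibble::tibble(x_nm = pts[, 1], y_nm = pts[, 2],
                                  z_nm = pts[, 3], diameter_nm = dia)
    } else if (kind == "shell") {
      r0 <- (radius_nm %||% (nx * px / 5))
      add <- shell_density(nx, nz, px, zs, r0 - thickness_nm / 2, r0 + thickness_nm / 2)
      dens <- dens + intensity * add
    } else {
      half_xy <- (nx / 2 - nx * margin_frac) * px
      half_z <- max((nz / 2 - 1.5) * zs, 0)
      for (f in seq_len(n)) {
        p <- c(stats::runif(2, -half_xy, half_xy), stats::runif(1, -half_z, half_z))
        ang <- stats::runif(1, 0, 2 * pi); dzs <- stats::runif(1, -0.1, 0.1)
        dirv <- c(cos(ang), sin(ang), dzs)
        step <- px
        for (s in seq_len(round(2.2 * half_xy / step))) {
          ang <- ang + stats::rnorm(1, 0, 0.05)
          dirv <- c(cos(ang), sin(ang), dirv[3] + stats::rnorm(1, 0, 0.01))
          p2 <- p + dirv / sqrt(sum(dirv^2)) * step
          if (max(abs(p2[1:2])) > half_xy || abs(p2[3]) > half_z) break
          dens <- add_bead(dens, p2, filament_sigma_nm, intensity,
                           px, zs, soft = TRUE)
          p <- p2
        }
      }
    }
  })
  structure(list(density = dens, kind = kind, positions = positions,
                 pixel_xy = px, z_step = zs), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("<phantom> kind '%s', %d x %d x %d, total mass %.4g\n",
              x$kind, d[1], d[2], d[3], sum(x$density)))
  invisible(x)
}

# Paint a sphere (or Gaussian splat) centered at `pos` nm (relative to the
# volume centre) into `dens`. Subsamples boundary voxels for mass accuracy.
add_bead <- function(dens, pos, radius_nm, intensity, px, zs, soft = FALSE) {
  d <- dim(dens)
  c_vox <- c(pos[2] / px + (d[1] / 2 + 0.5), pos[1] / px + (d[2] / 2 + 0.5),
             pos[3] / zs + (floor(d[3] / 2) + 1))
  if (soft) {
    # Gaussian splat with sigma = radius_nm
    rx <- ceiling(3 * radius_nm / px); rz <- ceiling(3 * radius_nm / zs)
    ii <- pmax(1, floor(c_vox[1]) - rx):pmin(d[1], ceiling(c_vox[1]) + rx)
    jj <- pmax(1, floor(c_vox[2]) - rx):pmin(d[2], ceiling(c_vox[2]) + rx)
    kk <- pmax(1, floor(c_vox[3]) - rz):pmin(d[3], ceiling(c_vox[3]) + rz)
    for (k in kk) {
      dz2 <- ((k - c_vox[3]) * zs)^2
      g <- outer(((ii - c_vox[1]) * px)^2, ((jj - c_vox[2]) * px)^2, `+`) + dz2
      dens[ii, jj, k] <- dens[ii, jj, k] + intensity * exp(-g / (2 * radius_nm^2))
    }
    return(dens)
  }
  rx <- ceiling(radius_nm / px) + 1; rz <- ceiling(radius_nm / zs) + 1
  ii <- pmax(1, floor(c_vox[1]) - rx):pmin(d[1], ceiling(c_vox[1]) + rx)
  jj <- pmax(1, floor(c_vox[2]) - rx):pmin(d[2], ceiling(c_vox[2]) + rx)
  kk <- pmax(1, floor(c_vox[3]) - rz):pmin(d[3], ceiling(c_vox[3]) + rz)
  ss <- (seq_len(5) - 3) / 5
  for (k in kk) for (j in jj) for (i in ii) {
    dxs <- (i + ss - c_vox[1]) * px
    dys <- (j + ss - c_vox[2]) * px
    dzs <- (k + ss - c_vox[3]) * zs
    r2 <- outer(outer(dxs^2, dys^2, `+`), dzs^2, `+`)
    frac <- mean(r2 <= radius_nm^2)
    if (frac > 0) dens[i, j, k] <- dens[i, j, k] + intensity * frac
  }
  dens
}

shell_density <- function(nx, nz, px, zs, r_in, r_out) {
  out <- array(0, c(nx, nx, nz))
  ss <- (seq_len(3) - 2) / 3
  xs <- (seq_len(nx) - (nx / 2 + 0.5)) * px
  zc <- z_coords(nz, zs)
  for (k in seq_len(nz)) for (j in seq_len(nx)) for (i in seq_len(nx)) {
    r0 <- sqrt(xs[i]^2 + xs[j]^2 + zc[k]^2)
    if (r0 < r_in - max(px, zs) || r0 > r_out + max(px, zs)) next
    r2 <- outer(outer((xs[i] + ss * px)^2, (xs[j] + ss * px)^2, `+`),
                (zc[k] + ss * zs)^2, `+`)
    # a voxel contributes only where its subsamples are at or beyond the
    # inner radius, so the interior stays exactly empty
    out[i, j, k] <- mean(r2 >= r_in^2 & r2 <= r_out^2)
  }
  out
}
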