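#' Sampled wavefront over a pupil
#'
#' A wavefront is an optical-path-difference map (micrometres) on a square
#' grid together with a boolean pupil mask. All statistics (peak-to-valley,
#' RMS/STD, mean) are computed over the mask only; values outside the mask
#' are ignored.
#'
#' @param phase Numeric matrix of OPD values (um).
#' @param mask Logical matrix of the same shape; `TRUE` inside the pupil.
#'   Default: the inscribed unit disk.
#' @param coords Optional list of matrices `x`, `y`: normalized pupil
#'   coordinates of each sample (pupil edge at radius 1). Used when the
#'   grid does not span exactly the pupil diameter (e.g. lenslet-sampled
#'   wavefronts). Default: the inscribed unit square `[-1, 1]^2`.
#' @return A `wavefront` object.
#' @export
wavefront <- function(phase, mask = NULL, coords = NULL) {
  stopifnot(is.matrix(phase), nrow(phase) == ncol(phase))
  if (is.null(mask)) mask <- unit_disk_grid(nrow(phase))$mask
  stopifnot(is.logical(mask), all(dim(mask) == dim(phase)))
  if (!all(is.finite(phase[mask]))) stop("wavefront has non-finite values inside the pupil", call. = FALSE)
  if (!is.null(coords)) stopifnot(all(dim(coords$x) == dim(phase)))
  structure(list(phase = phase, mask = mask, grid_size = nrow(phase),
                 coords = coords),
            class = "wavefront")
}

#' @export
print.wavefront <- function(x, ...) {
  cat(sprintf("<wavefront> %dx%d grid, PV %.4g um, STD %.4g um\n",
              x$grid_size, x$grid_size, wf_pv(x), wf_std(x)))
  invisible(x)
}

#' Wavefront statistics over the pupil mask
#'
#' `wf_pv()` is peak-to-valley (max - min), `wf_std()` the standard deviation
#' about the pupil mean, and `wf_mean()` the pupil mean, all in micrometres.
#'
#' @param w A [wavefront].
#' @return Scalar, um.
#' @export
wf_pv <- function(w) {
  v <- w$phase[w$mask]
  max(v) - min(v)
}

#' @rdname wf_pv
#' @export
wf_std <- function(w) {
  v <- w$phase[w$mask]
  sqrt(mean((v - mean(v))^2))
}

#' @rdname wf_pv
#' @export
wf_mean <- function(w) mean(w$phase[w$mask])

#' @export
`+.wavefront` <- function(e1, e2) {
  stopifnot(inherits(e1, "wavefront"), inherits(e2, "wavefront"),
            e1$grid_size == e2$grid_size)
  wavefront(e1$phase + e2$phase, e1$mask & e2$mask)
}

#' @export
`-.wavefront` <- function(e1, e2) {
  if (missing(e2)) return(wavefront(-e1$phase, e1$mask))
  stopifnot(inherits(e2, "wavefront"), e1$grid_size == e2$grid_size)
  wavefront(e1$phase - e2$phase, e1$mask & e2$mask)
}

#' Glance at a wavefront
#'
#' @param x A [wavefront].
#' @param ... Unused.
#' @return One-row tibble with grid size, PV, STD and mean (um).
#' @export
glance.wavefront <- function(x, ...) {
  tibble::tibble(grid_size = x$grid_size, n_pupil = sum(x$mask),
                 pv_um = wf_pv(x), std_um = wf_std(x), mean_um = wf_mean(x))
}

#' Tidy a wavefront into per-pixel records
#'
#' @param x A [wavefront].
#' @param ... Unused.
#' @return Tibble with normalized pupil coordinates `u`, `v` and `opd_um`,
#'   one row per pupil pixel.
#' @export
tidy.wavefront <- function(x, ...) {
  if (is.null(x$coords)) {
    g <- unit_disk_grid(x$grid_size)
    xx <- g$x; yy <- g$y
  } else {
    xx <- x$coords$x; yy <- x$coords$y
  }
  keep <- which(x$mask)
  tibble::tibble(u = xx[keep], v = yy[keep], opd_um = x$phase[keep])
}

#' Plot a wavefront as a filled raster
#'
#' @param object A [wavefront].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wavefront <- function(object, ...) {
  df <- tidy.wavefront(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v, fill = .data$opd_um)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_gradient2(name = "OPD (µm)") +
    ggplot2::labs(x = NULL, y = NULL, title = sprintf(
      "Wavefront: PV %.3f µm, STD %.3f µm", wf_pv(object), wf_std(object)))
}
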