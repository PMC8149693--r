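#' Write / read a raw SIM stack as multi-page TIFF
#'
#' Pages are 32-bit samples ordered z-fastest, then phase, then orientation
#' (`15 * n_z` pages for 3D-SIM), linearly scaled to the file range with the
#' original min/max recorded in a YAML sidecar `<path>.yml` alongside the
#' pattern and optical metadata; the round trip is lossless to 1 part in
#' 2^32.
#'
#' @param stack A [simulate_sim_stack] result.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_raw_stack <- function(stack, path) {
  stopifnot(inherits(stack, "sim_stack"))
  d <- dim(stack$data)
  pages <- vector("list", d[3] * d[4] * d[5])
  k <- 0
  lo <- min(stack$data); hi <- max(stack$data)
  scale <- if (hi > lo) hi - lo else 1
  for (j in seq_len(d[5])) for (p in seq_len(d[4])) for (z in seq_len(d[3])) {
    k <- k + 1
    pages[[k]] <- (stack$data[, , z, p, j] - lo) / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(
    range_min = lo, range_max = lo + scale,
    kind = "raw_sim_stack",
    axes = "page order: z fastest, then phase, then orientation",
    n_z = d[3], n_phase = d[4], n_orientation = d[5],
    pattern = unclass(stack$pattern)[c("period_nm", "orientations_deg",
                                       "phases_rad", "order_intensity_ratio",
                                       "phase_offset_rad")],
    optical = unclass(stack$config),
    seed = if (!is.null(stack$noise)) stack$noise$seed)
  yaml::write_yaml(meta, paste0(path, ".yml"), precision = 15L)
  invisible(path)
}

#' @rdname write_raw_stack
#' @param strict Error if the page count does not match the sidecar.
#' @return For `read_raw_stack`: a `sim_stack`.
#' @export
read_raw_stack <- function(path, strict = TRUE) {
  side <- paste0(path, ".yml")
  if (!file.exists(side)) {
    stop(sprintf(paste0("missing sidecar '%s': supply the pattern metadata ",
                        "(period_nm, orientations_deg, phases_rad, ",
                        "order_intensity_ratio) and optical config as YAML"),
                 side), call. = FALSE)
  }
  meta <- yaml::read_yaml(side)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  n_expect <- meta$n_z * meta$n_phase * meta$n_orientation
  if (length(pages) != n_expect) {
    stop(sprintf("page count mismatch: expected %d (= %d z x %d phases x %d orientations), found %d",
                 n_expect, meta$n_z, meta$n_phase, meta$n_orientation,
                 length(pages)), call. = FALSE)
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  lo <- meta$range_min %||% 0
  scale <- (meta$range_max %||% 1) - lo
  dat <- array(0, c(ny, nx, meta$n_z, meta$n_phase, meta$n_orientation))
  k <- 0
  for (j in seq_len(meta$n_orientation)) for (p in seq_len(meta$n_phase)) {
    for (z in seq_len(meta$n_z)) {
      k <- k + 1
      dat[, , z, p, j] <- pages[[k]] * scale + lo
    }
  }
  pat <- do.call(si_pattern, meta$pattern)
  oc <- meta$optical
  cfg <- optical_config(wavelength_em = oc$wavelength_em,
                        wavelength_ex = oc$wavelength_ex, na = oc$na,
                        n_immersion = oc$n_immersion, pixel_xy = oc$pixel_xy,
                        z_step = oc$z_step, grid_xy = oc$grid_xy, n_z = oc$n_z)
  structure(list(data = dat, pattern = pat, config = cfg,
                 true_aberration = NULL, noise = NULL),
            class = "sim_stack")
}

#' Write a real volume as multi-page 32-bit TIFF
#'
#' Page order is z; samples are linearly scaled to the file range and a
#' YAML sidecar records the original range and voxel sizes (round trip
#' lossless to 1 part in 2^32).
#'
#' @param volume Real array `(y, x, z)` (a matrix is written as one page).
#' @param path Output path.
#' @param pixel_xy,z_step Voxel sizes, nm (sidecar metadata).
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path, pixel_xy = NA, z_step = NA) {
  if (is.matrix(volume)) volume <- array(volume, c(dim(volume), 1))
  lo <- min(volume); hi <- max(volume)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(volume)[3]),
                  function(z) (volume[, , z] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  yaml::write_yaml(list(kind = "volume", axes = "(z pages, y rows, x cols)",
                        range_min = lo, range_max = lo + scale,
                        pixel_xy_nm = pixel_xy, z_step_nm = z_step),
                   paste0(path, ".yml"), precision = 15L)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @return For `read_volume_tiff`: the array `(y, x, z)`.
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- tryCatch(yaml::read_yaml(paste0(path, ".yml")), error = function(e) NULL)
  lo <- meta$range_min %||% 0
  scale <- (meta$range_max %||% 1) - lo
  out <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) out[, , z] <- pages[[z]] * scale + lo
  out
}

run_config_sections <- c("optical", "pattern", "recon", "ao", "shwfs", "seed")

#' Read / write a run configuration
#'
#' A flat YAML file with sections `optical` ([optical_config] fields),
#' `pattern` ([si_pattern]), `recon` ([recon_params]), `ao`
#' ([trial_schedule] fields), `shwfs` ([sh_geometry]) and a top-level
#' `seed`. Unknown sections or keys are rejected; the round trip through
#' [write_run_config] is lossless.
#'
#' @param path YAML file path.
#' @return A `run_config` list with constructed component objects.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), run_config_sections)
  if (length(bad)) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  build <- function(fun, args, what) {
    known <- names(formals(fun))
    extra <- setdiff(names(args), known)
    if (length(extra)) {
      stop(sprintf("unknown key(s) in '%s': %s", what,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    do.call(fun, args)
  }
  structure(list(
    optical = build(optical_config, raw$optical %||% list(), "optical"),
    pattern = build(si_pattern, raw$pattern %||% list(), "pattern"),
    recon = build(recon_params, raw$recon %||% list(), "recon"),
    ao = build(trial_schedule, raw$ao %||% list(), "ao"),
    shwfs = build(sh_geometry, raw$shwfs %||% list(), "shwfs"),
    seed = raw$seed %||% 1L), class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  yaml::write_yaml(list(optical = strip(config$optical),
                        pattern = strip(config$pattern),
                        recon = strip(config$recon),
                        ao = strip(config$ao),
                        shwfs = strip(config$shwfs),
                        seed = config$seed), path, precision = 15L)
  invisible(path)
}
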