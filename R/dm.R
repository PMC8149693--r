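#' Deformable-mirror model
#'
#' 69 actuators on a 9 x 9 lattice with the 12 extreme corners removed,
#' conjugated to a 10 mm pupil. Influence functions are Gaussians centred
#' on each actuator with inter-actuator coupling `coupling` (the response
#' at the neighbouring actuator relative to the centre), and the mirror
#' surface is linear in the command vector.
#'
#' @param n_actuators Must currently be 69 (the 9x9-minus-corners layout).
#' @param aperture_mm Pupil diameter on the mirror.
#' @param coupling Inter-actuator coupling (0..1).
#' @return A `dm_model` with actuator positions in normalized pupil units.
#' @export
dm_model <- function(n_actuators = 69, aperture_mm = 10, coupling = 0.3) {
  pos <- (-4):4 / 4  # 9 across the normalized pupil
  grid <- expand.grid(x = pos, y = pos)
  keep <- sqrt((grid$x * 4)^2 + (grid$y * 4)^2) <= 4.5
  grid <- grid[keep, ]
  if (nrow(grid) != n_actuators) {
    stop(sprintf("layout yields %d actuators; only the 69-actuator layout is supported",
                 nrow(grid)), call. = FALSE)
  }
  spacing <- 1 / 4
  sigma <- spacing / sqrt(2 * log(1 / coupling))
  structure(list(n_actuators = nrow(grid), aperture_mm = aperture_mm,
                 x = grid$x, y = grid$y, sigma = sigma, coupling = coupling),
            class = "dm_model")
}

#' @export
print.dm_model <- function(x, ...) {
  cat(sprintf("<dm_model> %d actuators, %g mm aperture, coupling %.2f (sigma %.3f)\n",
              x$n_actuators, x$aperture_mm, x$coupling, x$sigma))
  invisible(x)
}

# Influence matrix: response of every pupil sample (rows) to each actuator
# (columns), for unit command (um surface).
dm_influence_matrix <- function(dm, xx, yy) {
  n <- length(xx)
  A <- matrix(0, n, dm$n_actuators)
  for (a in seq_len(dm$n_actuators)) {
    A[, a] <- exp(-((xx - dm$x[a])^2 + (yy - dm$y[a])^2) / (2 * dm$sigma^2))
  }
  A
}

#' Render the mirror surface for a command vector
#'
#' @param dm A [dm_model].
#' @param commands Numeric vector of length `n_actuators` (um).
#' @param grid_size Output sampling; or supply `coords` + `mask`.
#' @param coords,mask Optional explicit sampling (as in [wavefront]).
#' @return A [wavefront] of the mirror contribution.
#' @export
dm_wavefront <- function(dm, commands, grid_size = 128, coords = NULL,
                         mask = NULL) {
  stopifnot(length(commands) == dm$n_actuators)
  if (is.null(coords)) {
    g <- unit_disk_grid(grid_size)
    coords <- list(x = g$x, y = g$y)
    mask <- mask %||% g$mask
  }
  A <- dm_influence_matrix(dm, as.vector(coords$x), as.vector(coords$y))
  ph <- matrix(A %*% commands, nrow(coords$x), ncol(coords$x))
  wavefront(ph, mask = mask, coords = coords)
}

#' Fit mirror commands to a target wavefront
#'
#' Least squares against the influence functions over the pupil mask. The
#' fit is a projection: refitting the rendered surface returns the same
#' commands.
#'
#' @param dm A [dm_model].
#' @param wf Target [wavefront] (um).
#' @return Command vector (um).
#' @export
dm_fit_commands <- function(dm, wf) {
  keep <- which(wf$mask)
  if (is.null(wf$coords)) {
    g <- unit_disk_grid(wf$grid_size)
    xx <- g$x; yy <- g$y
  } else {
    xx <- wf$coords$x; yy <- wf$coords$y
  }
  A <- dm_influence_matrix(dm, xx[keep], yy[keep])
  qr.solve(A, wf$phase[keep])
}

#' Closed-loop wavefront correction against the sensor
#'
#' Repeats: acquire a Shack-Hartmann frame under the current commands,
#' measure slopes against the reference, reconstruct the wavefront, remove
#' piston/tip/tilt/defocus, fit mirror commands to the residual and apply
#' them with the loop gain. The residual RMS is recorded per iteration; the
#' loop aborts with a diagnostic if the residual increases over three
#' consecutive iterations.
#'
#' @param sensor Function `commands -> sh_frame`: the plant (sample
#'   aberration plus mirror) as seen by the sensor. Deterministic for a
#'   fixed seed.
#' @param dm A [dm_model].
#' @param reference Aberration-free reference `sh_frame`.
#' @param n_iter Iterations.
#' @param gain Loop gain in (0, 1]; 0 freezes the commands.
#' @param n_modes Modes used for the piston/tip/tilt/defocus removal.
#' @return List with final `commands`, `history` tibble
#'   (iteration, residual RMS um), `converged`, and the last measured
#'   residual [wavefront].
#' @export
closed_loop_correct <- function(sensor, dm, reference, n_iter = 10,
                                gain = 0.5, n_modes = 15) {
  stopifnot(is.function(sensor), inherits(dm, "dm_model"))
  commands <- numeric(dm$n_actuators)
  hist <- numeric(0)
  wf_res <- NULL
  n_up <- 0
  for (it in seq_len(n_iter)) {
    frame <- sensor(commands)
    grads <- spot_gradients(frame, reference)
    wf <- ft_reconstruct_wavefront(grads, frame$geometry)
    cf <- decompose_to_zernike(wf, n_modes = n_modes)
    low <- coeffs_dense(cf, 4)[1:4]
    # subtract the non-corrected terms from the measured map
    ph <- wf$phase
    for (jm in 1:4) {
      if (low[jm] == 0) next
      zx <- zernike_eval(jm, sqrt(wf$coords$x^2 + wf$coords$y^2),
                         atan2(wf$coords$y, wf$coords$x))
      ph <- ph - low[jm] * zx
    }
    wf_res <- wavefront(ph * ifelse(wf$mask, 1, 0), mask = wf$mask,
                        coords = wf$coords)
    rms <- wf_std(wf_res)
    if (length(hist) && rms > hist[length(hist)]) n_up <- n_up + 1 else n_up <- 0
    hist <- c(hist, rms)
    if (n_up >= 3) {
      warning("closed loop diverging: residual increased over 3 consecutive iterations",
              call. = FALSE)
      break
    }
    if (gain > 0) {
      delta <- dm_fit_commands(dm, wf_res)
      commands <- commands - gain * delta
    }
  }
  list(commands = commands,
       history = tibble::tibble(iteration = seq_along(hist),
                                residual_rms_um = hist),
       converged = length(hist) >= 2 &&
         hist[length(hist)] <= 0.5 * hist[1],
       residual = wf_res)
}

#' Plot a closed-loop residual history
#'
#' @param history Tibble from [closed_loop_correct].
#' @return A ggplot of residual RMS vs iteration.
#' @export
plot_loop_history <- function(history) {
  ggplot2::ggplot(history, ggplot2::aes(x = .data$iteration,
                                        y = .data$residual_rms_um)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "iteration", y = "residual RMS (µm)")
}
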