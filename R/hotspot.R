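# Hot-spot trajectories expose platelets to extreme stress/exposure-time
# combinations; their stress waveforms are replayed on a computer-controlled
# cone-plate Hemodynamic Shearing Device (HSD) that applies uniform shear.

#' Rank hot-spot trajectories
#'
#' Orders trajectories by total stress accumulation (default) or by peak
#' scalar stress, descending; ties are broken by ascending `traj_id` so
#' the ranking is deterministic.
#'
#' @inheritParams check_ensemble
#' @param k Number of top trajectories to return; if larger than the
#'   ensemble, all are returned with a warning.
#' @param criterion `"total_sa"` (default) or `"peak_stress"`.
#' @return A tibble `traj_id`, `sa`, `peak_scalar_stress`, `criterion`,
#'   `value`, ordered by decreasing `value`.
#' @export
rank_hotspots <- function(ensemble, k = 4L,
                          criterion = c("total_sa", "peak_stress")) {
  criterion <- match.arg(criterion)
  stopifnot(k >= 1L)
  res <- stress_accumulation(ensemble)
  res$value <- if (criterion == "total_sa") res$sa else res$peak_scalar_stress
  res <- res |>
    dplyr::arrange(dplyr::desc(.data$value), .data$traj_id) |>
    dplyr::mutate(criterion = criterion) |>
    dplyr::select("traj_id", "sa", "peak_scalar_stress", "criterion", "value")
  if (k > nrow(res)) {
    warn(sprintf("k = %d exceeds ensemble size %d; returning all", k, nrow(res)))
    k <- nrow(res)
  }
  res[seq_len(k), ]
}

#' Extract a uniform-grid stress waveform from a trajectory
#'
#' Linearly interpolates the per-sample scalar stress onto a uniform time
#' grid spanning the trajectory's time support, producing the command
#' waveform a shearing device can replay. Interpolated values are clipped
#' at zero (scalar stress is nonnegative; clipping only guards float
#' noise). For `dt` no larger than the finest sample spacing the waveform
#' SA matches the trajectory SA within about one part in a hundred.
#'
#' @param traj A single-trajectory ensemble (one `traj_id`).
#' @param dt Uniform grid spacing (s); must not exceed the trajectory
#'   duration.
#' @return A tibble of class `dte_waveform` with columns `t` (s) and
#'   `stress_pa` (Pa); attributes `dt` and `provenance` (traj_id).
#' @export
extract_waveform <- function(traj, dt) {
  traj <- add_scalar_stress(traj)
  ids <- unique(traj$traj_id)
  if (length(ids) != 1L) abort("extract_waveform expects a single trajectory")
  stopifnot(dt > 0)
  dur <- max(traj$t) - min(traj$t)
  if (dt > dur) {
    abort(sprintf("dt = %g s exceeds trajectory duration %g s", dt, dur))
  }
  grid <- seq(min(traj$t), max(traj$t), by = dt)
  stress <- approx(traj$t, traj$sigma, xout = grid)$y
  out <- tibble::tibble(t = grid, stress_pa = pmax(stress, 0))
  structure(out, class = c("dte_waveform", class(out)),
            dt = dt, provenance = ids)
}

#' Cone-plate shearing-device calibration
#'
#' Small-angle cone-plate rheometry: a cone of angle `alpha` rotating at
#' `omega` over a plate filled with fluid of viscosity `mu` applies the
#' uniform shear stress `tau = mu * omega / alpha`, independent of radius.
#'
#' @param viscosity Fluid dynamic viscosity (Pa s), e.g. 0.0035 for blood
#'   analog media.
#' @param cone_angle Cone angle (rad); must be small (< 0.2 rad) for the
#'   uniform-shear approximation.
#' @param max_speed Maximum motor speed (rad/s).
#' @return An object of class `hsd_calibration`.
#' @export
hsd_calibration <- function(viscosity, cone_angle, max_speed = 1000) {
  stopifnot(viscosity > 0, cone_angle > 0, max_speed > 0)
  if (cone_angle >= 0.2) {
    abort("cone_angle must be below 0.2 rad for the small-angle mapping")
  }
  structure(list(viscosity = viscosity, cone_angle = cone_angle,
                 max_speed = max_speed), class = "hsd_calibration")
}

#' @export
print.hsd_calibration <- function(x, ...) {
  cat(sprintf("<hsd_calibration> mu %g Pa·s, cone %g rad, max %g rad/s\n",
              x$viscosity, x$cone_angle, x$max_speed))
  invisible(x)
}

#' Translate a stress waveform into an HSD speed schedule
#'
#' Inverts the cone-plate relation per step: `omega_i = tau_i * cone_angle
#' / viscosity`. The program is linear in stress, so scaling the waveform
#' scales the schedule. Errors if any required speed exceeds the motor
#' limit.
#'
#' @param waveform A `dte_waveform` (or any data frame with `t` and
#'   `stress_pa` columns).
#' @param cal An [hsd_calibration()].
#' @return A tibble `t` (s), `omega_rad_s` (rad/s), `rpm`.
#' @export
hsd_program <- function(waveform, cal) {
  stopifnot(inherits(cal, "hsd_calibration"))
  if (!all(c("t", "stress_pa") %in% names(waveform))) {
    abort("waveform must have columns t and stress_pa")
  }
  if (any(waveform$stress_pa < 0) || !all(is.finite(waveform$stress_pa))) {
    abort("waveform stresses must be finite and nonnegative")
  }
  omega <- waveform$stress_pa * cal$cone_angle / cal$viscosity
  if (any(omega > cal$max_speed)) {
    i <- which.max(omega)
    abort(sprintf(
      "peak stress %g Pa requires %g rad/s, above the %g rad/s motor limit",
      waveform$stress_pa[i], omega[i], cal$max_speed))
  }
  tibble::tibble(t = waveform$t, omega_rad_s = omega,
                 rpm = omega * 60 / (2 * pi))
}

#' Plot a stress-loading waveform
#'
#' @param object A `dte_waveform`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dte_waveform
#' @export
autoplot.dte_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$stress_pa)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "Time (s)", y = "Scalar stress (Pa)",
                  title = paste0("Stress-loading waveform (",
                                 attr(object, "provenance") %||% "waveform", ")"))
}
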