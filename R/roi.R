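#' Define a cylindrical region of interest
#'
#' Regions of interest (ROI) are cylindrical shells aligned with the device
#' rotation axis (z), described by half-open intervals in axial position
#' `z`, radius `r = sqrt(x^2 + y^2)` and, optionally, azimuth `theta`
#' (radians in `[0, 2*pi)`, measured from the x axis). Half-open intervals
#' make partitions of the device volume exact: a sample on a shared
#' boundary belongs to exactly one ROI.
#'
#' @param label Name of the region (e.g. "impeller", "tip-shroud gap").
#' @param z Numeric `c(z0, z1)`, metres along the axis, `z0 < z1`.
#' @param r Numeric `c(r0, r1)`, metres radially, `0 <= r0 < r1`.
#' @param theta Optional `c(theta0, theta1)` radians; a wrapped sector
#'   (`theta0 > theta1`) crosses the 0/2pi seam.
#' @return An object of class `"roi"`.
#' @export
roi <- function(label, z, r, theta = NULL) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(z), length(z) == 2L,
            is.numeric(r), length(r) == 2L)
  if (!(z[1] < z[2])) abort("roi: need z0 < z1")
  if (!(r[1] >= 0 && r[1] < r[2])) abort("roi: need 0 <= r0 < r1")
  if (!is.null(theta)) stopifnot(is.numeric(theta), length(theta) == 2L)
  structure(list(label = label, z = z, r = r, theta = theta), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi '%s'> z [%g, %g) m, r [%g, %g) m%s\n", x$label,
              x$z[1], x$z[2], x$r[1], x$r[2],
              if (is.null(x$theta)) "" else
                sprintf(", theta [%g, %g) rad", x$theta[1], x$theta[2])))
  invisible(x)
}

#' Read ROI definitions from a YAML or JSON config
#'
#' The config is a list of records `{label, z: [z0, z1], r: [r0, r1],
#' theta: [theta0, theta1]?}` in SI units.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of [roi()] objects, named by label.
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  out <- lapply(raw, function(x) {
    roi(x$label, as.numeric(x$z), as.numeric(x$r),
        if (is.null(x$theta)) NULL else as.numeric(x$theta))
  })
  setNames(out, vapply(out, `[[`, character(1), "label"))
}

in_roi <- function(x, y, z, region) {
  r <- sqrt(x^2 + y^2)
  ok <- z >= region$z[1] & z < region$z[2] &
    r >= region$r[1] & r < region$r[2]
  if (!is.null(region$theta)) {
    th <- atan2(y, x) %% (2 * pi)
    t0 <- region$theta[1]; t1 <- region$theta[2]
    ok <- ok & if (t0 <= t1) th >= t0 & th < t1 else th >= t0 | th < t1
  }
  ok
}

#' Restrict an ensemble to a region of interest
#'
#' Keeps exactly the samples whose position lies inside the ROI; SA of the
#' clipped ensemble therefore accumulates only over intervals retained in
#' the region. Trajectories with no sample in the ROI are dropped.
#' Membership is tested per sample, not by interpolating boundary
#' crossings, so very coarse time steps can miss brief passages.
#'
#' @inheritParams check_ensemble
#' @param region An [roi()] object.
#' @return The clipped ensemble tibble (possibly zero rows).
#' @export
clip_to_roi <- function(ensemble, region) {
  ensemble <- check_ensemble(ensemble)
  stopifnot(inherits(region, "roi"))
  dplyr::filter(ensemble, in_roi(.data$x, .data$y, .data$z, region))
}

#' Fraction of trajectories passing through a region of interest
#'
#' A trajectory "passes through" the ROI if at least one of its samples
#' lies inside it; the fraction is relative to all trajectories in the
#' ensemble.
#'
#' @inheritParams clip_to_roi
#' @return A single number in `[0, 1]`.
#' @export
roi_pass_fraction <- function(ensemble, region) {
  ensemble <- check_ensemble(ensemble)
  stopifnot(inherits(region, "roi"))
  inside <- in_roi(ensemble$x, ensemble$y, ensemble$z, region)
  length(unique(ensemble$traj_id[inside])) / length(unique(ensemble$traj_id))
}
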