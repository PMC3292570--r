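#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom stats approx aov lm coef quantile rlnorm rnorm runif sd
#'   t.test wilcox.test anova setNames
#' @importFrom utils head tail
NULL

# Column conventions for trajectory ensembles (SI units: s, m, Pa).
viscous_cols  <- c("sxx", "syy", "szz", "sxy", "sxz", "syz")
reynolds_cols <- c("rxx", "ryy", "rzz", "rxy", "rxz", "ryz")
coord_cols    <- c("traj_id", "t", "x", "y", "z")

#' Validate a trajectory ensemble data frame
#'
#' An ensemble is a long table of platelet trajectory samples with columns
#' `traj_id, t, x, y, z`, six viscous stress-tensor components
#' `sxx, syy, szz, sxy, sxz, syz` (Pa) and, optionally, six Reynolds
#' (turbulent) stress components `rxx, ryy, rzz, rxy, rxz, ryz` (Pa).
#' Within each trajectory, time must be strictly increasing and all
#' coordinates finite.
#'
#' @param ensemble A data frame of trajectory samples.
#' @return The validated ensemble as a tibble (invisibly usable in pipes).
#' @export
check_ensemble <- function(ensemble) {
  ensemble <- tibble::as_tibble(ensemble)
  need <- c(coord_cols, viscous_cols)
  missing <- setdiff(need, names(ensemble))
  if (length(missing) > 0L) {
    abort(paste0("ensemble is missing required columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(ensemble) == 0L) abort("ensemble has no rows")
  num <- intersect(c(need, reynolds_cols), names(ensemble))
  num <- setdiff(num, "traj_id")
  bad <- num[!vapply(ensemble[num], function(v) all(is.finite(v)), logical(1))]
  if (length(bad) > 0L) {
    abort(paste0("non-finite values in columns: ", paste(bad, collapse = ", ")))
  }
  dec <- ensemble |>
    dplyr::group_by(.data$traj_id) |>
    dplyr::summarise(ok = all(diff(.data$t) > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(dec) > 0L) {
    abort(paste0("time is not strictly increasing within trajectory: ",
                 paste(dec$traj_id, collapse = ", ")))
  }
  ensemble
}

check_tensor <- function(m, name = "tensor") {
  if (!is.matrix(m) || !identical(dim(m), c(3L, 3L))) {
    abort(paste0(name, " must be a 3x3 matrix"))
  }
  if (!all(is.finite(m))) abort(paste0(name, " has NaN/Inf entries"))
  tol <- 1e-9 * max(abs(m), 1e-300)
  asym <- abs(m - t(m)) > tol
  if (any(asym)) {
    ij <- which(asym, arr.ind = TRUE)
    comps <- apply(ij, 1L, function(k) paste0("[", k[1], ",", k[2], "]"))
    abort(paste0(name, " is not symmetric in components ",
                 paste(unique(comps), collapse = ", ")))
  }
  invisible(m)
}

#' Total stress tensor from viscous and Reynolds parts
#'
#' The total stress experienced by a platelet combines the viscous stress
#' with the turbulent (Reynolds) stress; both enter additively before any
#' scalar reduction.
#'
#' @param viscous Symmetric 3x3 viscous stress tensor (Pa).
#' @param reynolds Optional symmetric 3x3 Reynolds stress tensor (Pa);
#'   treated as zero when `NULL`.
#' @return Symmetric 3x3 total stress tensor (Pa).
#' @export
total_stress <- function(viscous, reynolds = NULL) {
  check_tensor(viscous, "viscous")
  if (is.null(reynolds)) return(viscous)
  check_tensor(reynolds, "reynolds")
  viscous + reynolds
}

#' Scalar stress from a symmetric stress tensor
#'
#' Reduces a symmetric total stress tensor to a single nonnegative
#' magnitude using a von Mises type invariant,
#' \deqn{\sigma = \frac{1}{\sqrt{3}}\sqrt{\sigma_{11}^2+\sigma_{22}^2+
#'   \sigma_{33}^2-\sigma_{11}\sigma_{22}-\sigma_{22}\sigma_{33}-
#'   \sigma_{11}\sigma_{33}+3(\sigma_{12}^2+\sigma_{13}^2+\sigma_{23}^2)},}
#' equal to \eqn{\sqrt{J_2}} of the deviatoric tensor. It is invariant
#' under rotation, vanishes for isotropic (pure pressure) states, and for a
#' pure shear with the single component \eqn{\sigma_{12}=\tau} equals
#' \eqn{|\tau|}.
#'
#' Either pass a single 3x3 matrix as `sxx`, or the six independent
#' components as (vectorised) numerics.
#'
#' @param sxx,syy,szz,sxy,sxz,syz Tensor components (Pa), vectorised; or a
#'   3x3 symmetric matrix as the sole argument.
#' @return Scalar stress (Pa), same length as the component vectors.
#' @export
#' @examples
#' scalar_stress(matrix(c(0, 5, 0, 5, 0, 0, 0, 0, 0), 3)) # pure shear -> 5
scalar_stress <- function(sxx, syy, szz, sxy, sxz, syz) {
  if (is.matrix(sxx) && missing(syy)) {
    check_tensor(sxx, "total")
    m <- sxx
    return(scalar_stress(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3]))
  }
  vals <- cbind(sxx, syy, szz, sxy, sxz, syz)
  if (!all(is.finite(vals))) abort("scalar_stress: NaN/Inf tensor components")
  sq <- sxx^2 + syy^2 + szz^2 - sxx * syy - syy * szz - sxx * szz +
    3 * (sxy^2 + sxz^2 + syz^2)
  # guard tiny negative values from cancellation
  sqrt(pmax(sq, 0)) / sqrt(3)
}

#' Add per-sample scalar stress to an ensemble
#'
#' Computes the total stress tensor (viscous plus Reynolds where present)
#' at each sample and appends its scalar invariant as column `sigma` (Pa).
#'
#' @inheritParams check_ensemble
#' @return The ensemble tibble with an added `sigma` column.
#' @export
add_scalar_stress <- function(ensemble) {
  ensemble <- check_ensemble(ensemble)
  tot <- ensemble[viscous_cols]
  if (all(reynolds_cols %in% names(ensemble))) {
    tot <- tot + ensemble[reynolds_cols]
  }
  ensemble$sigma <- scalar_stress(tot[[1]], tot[[2]], tot[[3]],
                                  tot[[4]], tot[[5]], tot[[6]])
  ensemble
}

sa_right_rectangle <- function(t, sigma) {
  if (length(t) < 2L) return(0)
  sum(sigma[-1L] * diff(t))
}

#' Stress accumulation along each trajectory
#'
#' Stress accumulation (SA) is the product-sum of instantaneous scalar
#' stress and exposure time along a trajectory,
#' \eqn{SA = \sum_i \sigma_i \Delta t_i} (Pa s), with \eqn{\sigma_i} the
#' scalar stress at the sample ending interval \eqn{i} and
#' \eqn{\Delta t_i = t_i - t_{i-1}} (right rectangle rule, matching solver
#' output reported at the end of each time step). Single-sample
#' trajectories carry no interval and get SA 0 with a warning.
#'
#' @inheritParams check_ensemble
#' @param cumulative If `TRUE`, include a list-column `cumulative` of
#'   per-trajectory tibbles `(t, sa_cum)` giving the running accumulation.
#' @return A tibble with one row per trajectory: `traj_id`, `sa` (Pa s),
#'   `residence_time` (s), `peak_scalar_stress` (Pa), `n_samples`.
#' @export
stress_accumulation <- function(ensemble, cumulative = FALSE) {
  ensemble <- add_scalar_stress(ensemble)
  res <- ensemble |>
    dplyr::group_by(.data$traj_id) |>
    dplyr::summarise(
      sa = sa_right_rectangle(.data$t, .data$sigma),
      residence_time = max(.data$t) - min(.data$t),
      peak_scalar_stress = max(.data$sigma),
      n_samples = dplyr::n(),
      .groups = "drop"
    )
  if (any(res$n_samples == 1L)) {
    warn(paste0("trajectories with a single sample have SA = 0: ",
                paste(res$traj_id[res$n_samples == 1L], collapse = ", ")))
  }
  if (cumulative) {
    res$cumulative <- ensemble |>
      dplyr::group_by(.data$traj_id) |>
      dplyr::group_map(~ tibble::tibble(
        t = .x$t,
        sa_cum = cumsum(c(0, .x$sigma[-1L] * diff(.x$t)))
      ))
  }
  res
}

#' Power-law stress accumulation
#'
#' Generalises linear SA to the power-law family used in blood-damage
#' modelling: \eqn{SA_{a,b} = (\sum_i \sigma_i^{a/b} \Delta t_i)^b}, which
#' reduces exactly to linear SA at \eqn{a=b=1} and for constant stress
#' \eqn{\sigma} over duration \eqn{T} equals \eqn{\sigma^a T^b}.
#'
#' @inheritParams check_ensemble
#' @param a,b Positive stress and time exponents.
#' @return A tibble `traj_id`, `sa_powerlaw` (units Pa^a s^b).
#' @export
powerlaw_sa <- function(ensemble, a = 1, b = 1) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L ||
      length(b) != 1L || a <= 0 || b <= 0) {
    abort("exponents a and b must be positive scalars")
  }
  ensemble <- add_scalar_stress(ensemble)
  ensemble |>
    dplyr::group_by(.data$traj_id) |>
    dplyr::summarise(
      sa_powerlaw = if (a == 1 && b == 1) {
        sa_right_rectangle(.data$t, .data$sigma)
      } else {
        sa_right_rectangle(.data$t, .data$sigma^(a / b))^b
      },
      .groups = "drop"
    )
}

#' Peak scalar stress per trajectory
#'
#' @inheritParams check_ensemble
#' @return A tibble `traj_id`, `peak_scalar_stress` (Pa).
#' @export
peak_stress <- function(ensemble) {
  add_scalar_stress(ensemble) |>
    dplyr::group_by(.data$traj_id) |>
    dplyr::summarise(peak_scalar_stress = max(.data$sigma), .groups = "drop")
}
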