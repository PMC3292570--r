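# Platelet Activity State (PAS) assays report thrombin-generation-based
# platelet activation, normalized to the fully activated (sonicated)
# maximum, from timed flow-loop samples. The Platelet Activation Rate
# (PAR) is the slope of the linear fit of PAS versus time (min^-1).

#' Normalize raw PAS readings to the sonicated maximum
#'
#' @param raw Raw assay signal(s); nonnegative, not above `sonicated_max`.
#' @param sonicated_max Positive signal of the fully activated (sonicated)
#'   control; scalar or same length as `raw`.
#' @return Normalized PAS fraction(s) in `[0, 1]`.
#' @export
normalize_pas <- function(raw, sonicated_max) {
  if (any(sonicated_max <= 0)) abort("sonicated_max must be positive")
  if (any(raw < 0)) abort("raw PAS signal must be nonnegative")
  frac <- raw / sonicated_max
  if (any(frac > 1)) abort("raw PAS signal exceeds the sonicated maximum")
  frac
}

check_pas <- function(pas) {
  pas <- tibble::as_tibble(pas)
  need <- c("donor_id", "t_min", "pas")
  missing <- setdiff(need, names(pas))
  if (length(missing) > 0L) {
    abort(paste0("PAS data is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (any(pas$t_min < 0)) abort("timepoints must be nonnegative minutes")
  if (any(pas$pas < 0 | pas$pas > 1)) abort("pas must be a fraction in [0, 1]")
  pas
}

per_donor_slopes <- function(pas) {
  pas |>
    dplyr::group_by(.data$donor_id) |>
    dplyr::summarise(
      n_timepoints = dplyr::n_distinct(.data$t_min),
      slope = if (dplyr::n_distinct(.data$t_min) >= 2L) {
        unname(coef(lm(pas ~ t_min, data = dplyr::pick(dplyr::everything())))[2])
      } else NA_real_,
      .groups = "drop"
    )
}

#' Fit the Platelet Activation Rate (PAR)
#'
#' Ordinary least squares of PAS on time (minutes), pooled over donors of
#' one condition, with a free intercept (baseline activation exists in
#' real assays). When two or more donors are present, per-donor slopes are
#' also fitted; these are the experimental units for [compare_par()].
#'
#' @param pas A PAS table with columns `donor_id`, `t_min`, `pas` for a
#'   single condition; at least 2 distinct timepoints.
#' @return An object of class `par_fit` with elements `slope` (min^-1),
#'   `intercept`, `slope_se`, `n_points`, `n_donors`, `per_donor` (tibble
#'   of per-donor slopes or `NULL`), and the fitted `lm` as `fit`.
#' @export
fit_par <- function(pas) {
  pas <- check_pas(pas)
  if (dplyr::n_distinct(pas$t_min) < 2L) {
    abort("fit_par needs at least 2 distinct timepoints")
  }
  fit <- lm(pas ~ t_min, data = pas)
  sm <- summary(fit)$coefficients
  n_donors <- dplyr::n_distinct(pas$donor_id)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    slope_se = unname(sm["t_min", "Std. Error"]),
    n_points = nrow(pas),
    n_donors = n_donors,
    per_donor = if (n_donors >= 2L) per_donor_slopes(pas) else NULL,
    fit = fit,
    data = pas
  ), class = "par_fit")
}

#' @export
print.par_fit <- function(x, ...) {
  cat(sprintf("<par_fit> PAR = %.3g min^-1 (se %.2g), intercept %.3g; %d points, %d donor(s)\n",
              x$slope, x$slope_se, x$intercept, x$n_points, x$n_donors))
  invisible(x)
}

#' Tidy a PAR fit
#'
#' @param x A `par_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std_error`.
#' @method tidy par_fit
#' @export
tidy.par_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std_error = unname(sm[, "Std. Error"]))
}

#' One-row summary of a PAR fit
#'
#' @inheritParams tidy.par_fit
#' @return A one-row tibble: `slope` (min^-1), `slope_se`, `intercept`,
#'   `r_squared`, `n_points`, `n_donors`.
#' @method glance par_fit
#' @export
glance.par_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, slope_se = x$slope_se,
                 intercept = x$intercept,
                 r_squared = summary(x$fit)$r.squared,
                 n_points = x$n_points, n_donors = x$n_donors)
}

#' Plot a PAR fit as mean +/- SEM per timepoint with the fitted line
#'
#' @param object A `par_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot par_fit
#' @export
autoplot.par_fit <- function(object, ...) {
  agg <- object$data |>
    dplyr::group_by(.data$t_min) |>
    dplyr::summarise(mean = mean(.data$pas),
                     sem = sd(.data$pas) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$t_min, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.5, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = "Time (min)", y = "PAS (fraction of sonicated max)",
                  title = sprintf("PAR = %.3g min^-1", object$slope))
}

#' Compare Platelet Activation Rates between conditions
#'
#' The default test is one-way ANOVA on per-donor slope estimates, with
#' the donor as the experimental unit (pairwise when two conditions are
#' supplied). Donors with fewer than 2 distinct timepoints are excluded
#' with a warning. `method = "interaction"` instead tests the
#' time-by-condition interaction in a pooled linear model
#' (`pas ~ t_min * condition`), a more powerful alternative that treats
#' individual measurements as units.
#'
#' @param pas A PAS table with columns `donor_id`, `condition`, `t_min`,
#'   `pas` covering two or more conditions.
#' @param method `"anova"` (per-donor slopes, default) or `"interaction"`.
#' @return A one-row tibble: `method`, `statistic` (F), `df1`, `df2`,
#'   `p_value`, `n_groups`.
#' @export
compare_par <- function(pas, method = c("anova", "interaction")) {
  method <- match.arg(method)
  pas <- check_pas(pas)
  if (!"condition" %in% names(pas)) abort("PAS data needs a 'condition' column")
  pas$condition <- factor(pas$condition)
  if (nlevels(pas$condition) < 2L) abort("need at least 2 conditions")
  if (method == "anova") {
    slopes <- pas |>
      dplyr::group_by(.data$condition) |>
      dplyr::group_modify(~ per_donor_slopes(.x)) |>
      dplyr::ungroup()
    dropped <- slopes |> dplyr::filter(is.na(.data$slope))
    if (nrow(dropped) > 0L) {
      warn(paste0("excluding donors with < 2 timepoints: ",
                  paste(dropped$donor_id, collapse = ", ")))
      slopes <- dplyr::filter(slopes, !is.na(.data$slope))
    }
    usable <- table(slopes$condition)
    if (any(usable < 2L)) {
      abort("each condition needs at least 2 donors with >= 2 timepoints")
    }
    av <- anova(aov(slope ~ condition, data = slopes))
    tibble::tibble(method = method,
                   statistic = av$`F value`[1],
                   df1 = av$Df[1], df2 = av$Df[2],
                   p_value = av$`Pr(>F)`[1],
                   n_groups = nlevels(pas$condition))
  } else {
    full <- lm(pas ~ t_min * condition, data = pas)
    reduced <- lm(pas ~ t_min + condition, data = pas)
    av <- anova(reduced, full)
    tibble::tibble(method = method,
                   statistic = av$F[2],
                   df1 = av$Df[2], df2 = full$df.residual,
                   p_value = av$`Pr(>F)`[2],
                   n_groups = nlevels(pas$condition))
  }
}

#' Ratio of two Platelet Activation Rates
#'
#' The thrombogenicity improvement factor between designs: slope of A over
#' slope of B, with a delta-method standard error from the two fits.
#'
#' @param fit_a,fit_b `par_fit` objects.
#' @return A one-row tibble: `ratio`, `se`.
#' @export
par_ratio <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "par_fit"), inherits(fit_b, "par_fit"))
  if (fit_b$slope == 0) abort("denominator PAR is zero")
  ratio <- fit_a$slope / fit_b$slope
  se <- abs(ratio) * sqrt((fit_a$slope_se / fit_a$slope)^2 +
                          (fit_b$slope_se / fit_b$slope)^2)
  tibble::tibble(ratio = ratio, se = se)
}
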