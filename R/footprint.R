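# The "thrombogenic footprint" of a device: the probability density of
# per-trajectory stress accumulation values, optionally bootstrapped up to
# a physiologically relevant platelet count so footprints from ensembles
# of different sizes are comparable.

as_sa_vector <- function(sa, what = "sa") {
  if (is.data.frame(sa)) {
    if (!"sa" %in% names(sa)) abort("data frame input must have an 'sa' column")
    sa <- sa$sa
  }
  if (!is.numeric(sa) || length(sa) == 0L) {
    abort(paste0(what, " must be a nonempty numeric vector (or data frame with an 'sa' column)"))
  }
  if (!all(is.finite(sa))) abort(paste0(what, " contains non-finite values"))
  sa
}

#' Per-trajectory SA population of an ensemble
#'
#' One stress-accumulation value per trajectory, the raw material of the
#' footprint PDF.
#'
#' @inheritParams check_ensemble
#' @return A tibble `traj_id`, `sa` (Pa s).
#' @export
sa_population <- function(ensemble) {
  res <- stress_accumulation(ensemble)
  res[c("traj_id", "sa")]
}

# Freedman-Diaconis bin edges spanning the data range exactly.
fd_edges <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(c(rng[1] - 0.5, rng[1] + 0.5))
  nb <- max(grDevices::nclass.FD(x), 1L)
  seq(rng[1], rng[2], length.out = nb + 1L)
}

bin_counts <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  if (any(idx == 0L | idx > length(edges) - 1L)) {
    abort("values fall outside the bin edges")
  }
  tabulate(idx, nbins = length(edges) - 1L)
}

new_footprint_pdf <- function(bin_edges, density, summary, n_source,
                              n_target = n_source, boot_reps = 0L,
                              ci_lower = NULL, ci_upper = NULL,
                              boot_mean = NA_real_) {
  structure(list(bin_edges = bin_edges, density = density,
                 ci_lower = ci_lower, ci_upper = ci_upper,
                 summary = summary, n_source = n_source,
                 n_target = n_target, boot_reps = boot_reps,
                 boot_mean = boot_mean),
            class = "footprint_pdf")
}

#' Summary statistics of an SA population
#'
#' Mean, standard deviation (n-1 denominator), skewness and Fisher excess
#' kurtosis (moment estimators, normal = 0), maximum, and Tukey outliers
#' (values outside `Q1 - 1.5 IQR` or `Q3 + 1.5 IQR`). Heavy-tailed,
#' log-normal-like SA populations typically show high kurtosis and a tail
#' of outlier values; these are flagged, not removed.
#'
#' @param sa Numeric vector of SA values (Pa s), or a data frame with an
#'   `sa` column such as from [sa_population()]; at least 2 values.
#' @return A one-row tibble: `n`, `mean`, `sd`, `skewness`,
#'   `excess_kurtosis`, `max`, `n_outliers`, and a list-column `outliers`.
#' @export
sa_summary <- function(sa) {
  sa <- as_sa_vector(sa)
  if (length(sa) < 2L) abort("sa_summary needs at least 2 values")
  q <- quantile(sa, c(0.25, 0.75), names = FALSE)
  fence <- c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
  out <- sa[sa < fence[1] | sa > fence[2]]
  tibble::tibble(
    n = length(sa),
    mean = mean(sa),
    sd = sd(sa),
    skewness = e1071::skewness(sa, type = 1),
    excess_kurtosis = e1071::kurtosis(sa, type = 1),
    max = max(sa),
    n_outliers = length(out),
    outliers = list(sort(out))
  )
}

#' Build a footprint PDF from SA values
#'
#' Bins the SA population into a normalized histogram density. Default
#' binning is Freedman-Diaconis over the data range; pass explicit edges
#' (e.g. shared edges from pooled data) to make two footprints directly
#' comparable bin by bin.
#'
#' @inheritParams sa_summary
#' @param breaks `NULL` for Freedman-Diaconis, a single integer bin count,
#'   or a strictly increasing numeric vector of bin edges (Pa s) spanning
#'   the data.
#' @return A `footprint_pdf` object; see [tidy.footprint_pdf()] and
#'   [glance.footprint_pdf()].
#' @export
build_pdf <- function(sa, breaks = NULL) {
  sa <- as_sa_vector(sa)
  if (any(sa < 0)) abort("SA values must be nonnegative")
  edges <- resolve_edges(sa, breaks)
  counts <- bin_counts(sa, edges)
  dens <- counts / (length(sa) * diff(edges))
  smry <- if (length(sa) >= 2L) sa_summary(sa) else NULL
  new_footprint_pdf(edges, dens, smry, n_source = length(sa))
}

resolve_edges <- function(sa, breaks) {
  if (is.null(breaks)) return(fd_edges(sa))
  if (length(breaks) == 1L) {
    rng <- range(sa)
    if (diff(rng) == 0) return(c(rng[1] - 0.5, rng[1] + 0.5))
    return(seq(rng[1], rng[2], length.out = breaks + 1L))
  }
  if (any(diff(breaks) <= 0)) abort("bin edges must be strictly increasing")
  breaks
}

#' Bootstrap a footprint PDF to a target population size
#'
#' Harmonizes footprints computed from ensembles of unequal size (a few
#' thousand seeded platelets) to a common, physiologically relevant
#' platelet count: each replicate resamples `target_n` SA values with
#' replacement, is binned on edges fixed from the source sample, and the
#' reported density is the mean over replicates with 2.5/97.5 percentile
#' confidence bands per bin.
#'
#' @inheritParams build_pdf
#' @param target_n Population size drawn in each replicate (>= 1).
#' @param boot_reps Number of bootstrap replicates (>= 1; default 1000).
#' @param seed Optional integer; fixes the resampling stream so the result
#'   is bit-for-bit reproducible without touching the global RNG state.
#' @return A `footprint_pdf` with `ci_lower`/`ci_upper` per bin and
#'   `boot_mean`, the grand mean of replicate sample means.
#' @export
bootstrap_pdf <- function(sa, target_n, boot_reps = 1000L, seed = NULL,
                          breaks = NULL) {
  sa <- as_sa_vector(sa)
  if (any(sa < 0)) abort("SA values must be nonnegative")
  stopifnot(target_n >= 1L, boot_reps >= 1L)
  edges <- resolve_edges(sa, breaks)
  widths <- diff(edges)
  run <- function() {
    dens <- matrix(0, nrow = boot_reps, ncol = length(widths))
    means <- numeric(boot_reps)
    for (r in seq_len(boot_reps)) {
      xb <- sa[sample.int(length(sa), target_n, replace = TRUE)]
      dens[r, ] <- bin_counts(xb, edges) / (target_n * widths)
      means[r] <- mean(xb)
    }
    list(dens = dens, means = means)
  }
  reps <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ci <- apply(reps$dens, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  smry <- if (length(sa) >= 2L) sa_summary(sa) else NULL
  new_footprint_pdf(edges, colMeans(reps$dens), smry,
                    n_source = length(sa), n_target = as.integer(target_n),
                    boot_reps = as.integer(boot_reps),
                    ci_lower = ci[1L, ], ci_upper = ci[2L, ],
                    boot_mean = mean(reps$means))
}

#' Compare two thrombogenic footprints
#'
#' Tests for a shift between two SA populations. SA populations are
#' typically heavy-tailed (close to log-normal), so the default is the
#' two-sided Mann-Whitney rank test; `"log_t"` performs a Welch t-test on
#' log-transformed values (all values must be positive). The reported
#' `mean_shift` is `mean(A) - mean(B)` on the raw Pa s scale and
#' `direction` names the group with the lower mean.
#'
#' @param sa_a,sa_b SA populations (numeric vectors or data frames with an
#'   `sa` column), each with at least 3 values.
#' @param method `"rank"` (Mann-Whitney, default) or `"log_t"` (Welch t on
#'   logs).
#' @return A one-row tibble: `method`, `statistic`, `p_value`,
#'   `mean_shift` (Pa s), `direction` (`"A_lower"`, `"B_lower"`, `"none"`).
#' @export
compare_footprints <- function(sa_a, sa_b, method = c("rank", "log_t")) {
  method <- match.arg(method)
  a <- as_sa_vector(sa_a, "sa_a")
  b <- as_sa_vector(sa_b, "sa_b")
  if (length(a) < 3L || length(b) < 3L) {
    abort("each population needs at least 3 values")
  }
  ht <- if (method == "rank") {
    wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
  } else {
    if (any(a <= 0) || any(b <= 0)) {
      abort("log_t requires strictly positive SA values")
    }
    t.test(log(a), log(b), var.equal = FALSE)
  }
  shift <- mean(a) - mean(b)
  tibble::tibble(
    method = method,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    mean_shift = shift,
    direction = if (shift < 0) "A_lower" else if (shift > 0) "B_lower" else "none"
  )
}

#' Compare two designs within each region of interest
#'
#' Clips both ensembles to each ROI, computes the per-trajectory SA
#' populations and runs [compare_footprints()] per region. P-values are
#' reported unadjusted by default; `adjust = "bonferroni"` multiplies by
#' the number of regions.
#'
#' @param ensemble_a,ensemble_b Trajectory ensembles for the two designs.
#' @param rois A list of [roi()] objects (e.g. from [read_roi()]).
#' @inheritParams compare_footprints
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return A tibble with one row per ROI: `label`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, plus the [compare_footprints()] columns.
#' @export
compare_roi_footprints <- function(ensemble_a, ensemble_b, rois,
                                   method = c("rank", "log_t"),
                                   adjust = c("none", "bonferroni")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  res <- purrr::map_dfr(rois, function(region) {
    a <- sa_population(clip_to_roi(ensemble_a, region))
    b <- sa_population(clip_to_roi(ensemble_b, region))
    cmp <- compare_footprints(a, b, method = method)
    tibble::tibble(label = region$label, n_a = nrow(a), n_b = nrow(b),
                   mean_a = mean(a$sa), mean_b = mean(b$sa)) |>
      dplyr::bind_cols(cmp)
  })
  if (adjust == "bonferroni") {
    res$p_value <- pmin(res$p_value * nrow(res), 1)
  }
  res
}

#' @export
print.footprint_pdf <- function(x, ...) {
  cat(sprintf("<footprint_pdf> %d bins on [%g, %g] Pa.s; n_source %d",
              length(x$density), min(x$bin_edges), max(x$bin_edges),
              x$n_source))
  if (x$boot_reps > 0L) {
    cat(sprintf("; bootstrapped to n = %d (%d reps)", x$n_target, x$boot_reps))
  }
  cat("\n")
  if (!is.null(x$summary)) {
    cat(sprintf("  mean %.3g  sd %.3g  skew %.3g  ex.kurtosis %.3g  max %.3g  outliers %d\n",
                x$summary$mean, x$summary$sd, x$summary$skewness,
                x$summary$excess_kurtosis, x$summary$max, x$summary$n_outliers))
  }
  invisible(x)
}

#' Tidy a footprint PDF into a per-bin tibble
#'
#' @param x A `footprint_pdf`.
#' @param ... Unused.
#' @return A tibble with one row per bin: `bin_left`, `bin_right`,
#'   `midpoint`, `density`, and `ci_lower`/`ci_upper` when bootstrapped.
#' @method tidy footprint_pdf
#' @export
tidy.footprint_pdf <- function(x, ...) {
  out <- tibble::tibble(
    bin_left = head(x$bin_edges, -1L),
    bin_right = tail(x$bin_edges, -1L),
    midpoint = (head(x$bin_edges, -1L) + tail(x$bin_edges, -1L)) / 2,
    density = x$density
  )
  if (!is.null(x$ci_lower)) {
    out$ci_lower <- x$ci_lower
    out$ci_upper <- x$ci_upper
  }
  out
}

#' One-row summary of a footprint PDF
#'
#' @inheritParams tidy.footprint_pdf
#' @return A one-row tibble combining the population summary statistics
#'   with `n_source`, `n_target`, `boot_reps` and `boot_mean`.
#' @method glance footprint_pdf
#' @export
glance.footprint_pdf <- function(x, ...) {
  smry <- if (is.null(x$summary)) {
    tibble::tibble(n = x$n_source)
  } else {
    dplyr::select(x$summary, -"outliers")
  }
  dplyr::bind_cols(smry, tibble::tibble(
    n_source = x$n_source, n_target = x$n_target,
    boot_reps = x$boot_reps, boot_mean = x$boot_mean))
}

#' Plot a thrombogenic footprint
#'
#' Step plot of the binned SA density with the bootstrap confidence band
#' when present.
#'
#' @param object A `footprint_pdf`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot footprint_pdf
#' @export
autoplot.footprint_pdf <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint, y = .data$density))
  if (!is.null(object$ci_lower)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      fill = "steelblue", alpha = 0.3)
  }
  p + ggplot2::geom_step(colour = "steelblue") +
    ggplot2::labs(x = "Stress accumulation (Pa·s)", y = "Density",
                  title = "Thrombogenic footprint")
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
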