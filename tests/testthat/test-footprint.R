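test_that("sa_population returns one closed-form SA per trajectory", {
  ens <- dplyr::bind_rows(
    pure_shear_traj(seq(0, 0.1, length.out = 5), 10, "a"),
    pure_shear_traj(seq(0, 0.2, length.out = 5), 10, "b"),
    pure_shear_traj(seq(0, 0.3, length.out = 5), 10, "c")
  )
  expect_equal(sa_population(ens)$sa, c(1, 2, 3))
  # mixed random fixture vs independent per-trajectory loop
  set.seed(81)
  mixed <- dplyr::bind_rows(lapply(1:5, function(i) {
    t <- sort(runif(12, 0, 0.4))
    pure_shear_traj(t, runif(12, 0, 300), traj_id = sprintf("m%d", i))
  }))
  pop <- sa_population(mixed)
  oracle <- vapply(pop$traj_id, function(id) {
    tr <- mixed[mixed$traj_id == id, ]
    sa_oracle(tr$t, tr$sxy)
  }, numeric(1))
  expect_equal(pop$sa, unname(oracle))
})

test_that("footprint density is normalized on every construction path", {
  set.seed(82)
  sa <- rlnorm(400, 1, 0.8)
  for (pdf in list(build_pdf(sa),
                   build_pdf(sa, breaks = 17),
                   build_pdf(sa, breaks = c(0, 1, 2, 5, 50)),
                   build_pdf(5), # single value
                   bootstrap_pdf(sa, 200, boot_reps = 40, seed = 9))) {
    expect_equal(sum(pdf$density * diff(pdf$bin_edges)), 1, tolerance = 1e-9)
    expect_true(all(pdf$density >= 0))
    expect_true(all(diff(pdf$bin_edges) > 0))
  }
  expect_error(build_pdf(c(1, -2)), "nonnegative")
})

test_that("a large uniform sample yields a flat density", {
  set.seed(83)
  pdf <- build_pdf(runif(50000), breaks = 20)
  # per-bin binomial sd ~ 0.02 at this size; allow 5 sigma
  expect_true(all(abs(pdf$density - 1) < 0.1))
})

test_that("summary statistics match hand and brute-force oracles", {
  s <- sa_summary(c(1, 2, 3, 4, 100))
  expect_equal(s$mean, 22)
  expect_equal(s$sd, 43.6176569751288)
  expect_equal(s$outliers[[1]], 100)

  s0 <- sa_summary(rep(7, 10))
  expect_equal(s0$sd, 0)
  expect_equal(s0$n_outliers, 0L)

  set.seed(84)
  x <- rlnorm(500, 0.5, 0.6)
  s1 <- sa_summary(x)
  n <- length(x); m <- sum(x) / n
  cm <- function(k) sum((x - m)^k) / n      # brute-force central moments
  expect_equal(s1$mean, m)
  expect_equal(s1$sd, sqrt(sum((x - m)^2) / (n - 1)))
  expect_equal(s1$skewness, cm(3) / cm(2)^1.5)
  expect_equal(s1$excess_kurtosis, cm(4) / cm(2)^2 - 3)
  expect_equal(s1$max, max(x))

  set.seed(85)
  expect_lt(abs(sa_summary(rnorm(50000))$excess_kurtosis), 0.1)
  expect_error(sa_summary(5), "at least 2")
})

test_that("bootstrap preserves the empirical mean and is reproducible", {
  set.seed(86)
  sa <- rlnorm(800, 1.2, 0.9)
  bp <- bootstrap_pdf(sa, target_n = 2000, boot_reps = 200, seed = 123)
  se_bound <- 3 * sd(sa) / sqrt(2000 * 200)
  expect_lt(abs(bp$boot_mean - mean(sa)), se_bound)
  expect_identical(bootstrap_pdf(sa, 2000, 200, seed = 123), bp)

  degen <- bootstrap_pdf(rep(4, 20), target_n = 50, boot_reps = 30, seed = 1)
  expect_length(degen$density, 1L)
  expect_equal(degen$ci_lower, degen$ci_upper)
})

test_that("tidy and glance expose per-bin and one-row views", {
  set.seed(87)
  bp <- bootstrap_pdf(rlnorm(300, 1, 0.5), 500, boot_reps = 50, seed = 4)
  td <- tidy(bp)
  expect_named(td, c("bin_left", "bin_right", "midpoint", "density",
                     "ci_lower", "ci_upper"))
  expect_equal(nrow(td), length(bp$density))
  expect_true(all(td$ci_lower <= td$ci_upper))
  gl <- glance(bp)
  expect_equal(gl$n_target, 500L)
  expect_equal(gl$mean, bp$summary$mean)
  expect_s3_class(autoplot(bp), "ggplot")
})

test_that("footprint comparison detects shifts and honours its contracts", {
  set.seed(88)
  x <- rlnorm(200, 1, 0.5)
  same <- compare_footprints(x, x)
  expect_gt(same$p_value, 0.9)
  expect_equal(same$mean_shift, 0)
  expect_equal(same$direction, "none")

  a <- rlnorm(1000, lognormal_match(16.2, 14.4)[1], lognormal_match(16.2, 14.4)[2])
  b <- rlnorm(1000, lognormal_match(3.5, 3.3)[1], lognormal_match(3.5, 3.3)[2])
  for (m in c("rank", "log_t")) {
    cmp <- compare_footprints(b, a, method = m)
    expect_lt(cmp$p_value, 0.01)
    expect_equal(cmp$direction, "A_lower")
  }
  expect_error(compare_footprints(c(0, 1, 2), c(1, 2, 3), method = "log_t"),
               "positive")
  expect_error(compare_footprints(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("per-ROI comparison reports each region, optionally Bonferroni-adjusted", {
  set.seed(89)
  ens_a <- preset_ensemble(device_preset("original"), n = 150, seed = 1)
  ens_b <- preset_ensemble(device_preset("optimized"), n = 150, seed = 2)
  rois <- list(roi("lower", z = c(0, 0.015), r = c(0, 1)),
               roi("upper", z = c(0.015, 1), r = c(0, 1)))
  res <- compare_roi_footprints(ens_a, ens_b, rois)
  expect_equal(res$label, c("lower", "upper"))
  expect_true(all(res$p_value < 0.01))
  adj <- compare_roi_footprints(ens_a, ens_b, rois, adjust = "bonferroni")
  expect_equal(adj$p_value, pmin(res$p_value * 2, 1))
})
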