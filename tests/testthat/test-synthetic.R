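test_that("uniform fields advect seeds on straight lines with zero stress", {
  f <- flow_field("uniform", U = c(1, 2, 0.5))
  ens <- advect(f, data.frame(x = 0, y = 0, z = 0), dt = 0.1, T_total = 1)
  expect_equal(ens$x, ens$t * 1)
  expect_equal(ens$y, ens$t * 2)
  expect_equal(ens$z, ens$t * 0.5)
  expect_true(all(ens$sxy == 0))
})

test_that("solid-body rotation conserves radius at fourth order", {
  f <- flow_field("solid_body_rotation", omega = 2 * pi)
  drift <- function(dt) {
    ens <- advect(f, data.frame(x = 0.01, y = 0, z = 0), dt = dt,
                  T_total = 10)                      # 10 full turns
    max(abs(sqrt(ens$x^2 + ens$y^2) / 0.01 - 1))
  }
  expect_lt(drift(1e-3), 1e-8)
  # halving dt cuts the drift by at least the 4th-order factor of 16
  # (the amplitude error of this scheme on circular orbits decays faster
  # still, about 32x per halving)
  ratio <- drift(4e-3) / drift(2e-3)
  expect_gt(ratio, 12)
  expect_lt(ratio, 48)
})

test_that("plane Couette trajectories have the closed-form stress mu*U/h", {
  f <- flow_field("couette", U = 1, h = 1e-3, mu = 0.0035)
  seeds <- data.frame(x = 0, y = c(2.5e-4, 5e-4, 7.5e-4), z = 0)
  ens <- advect(f, seeds, dt = 0.01, T_total = 1)
  expect_true(all(add_scalar_stress(ens)$sigma == 3.5))
  expect_equal(stress_accumulation(ens)$sa, rep(3.5, 3))
  expect_error(advect(f, data.frame(x = 0, y = 2e-3, z = 0), 0.01, 1),
               "outside")
})

test_that("annular-gap stress matches the circular Couette solution", {
  mu <- 0.0035; ri <- 0.01; ro <- 0.02; om <- 100
  f <- flow_field("annular_gap", omega = om, r_inner = ri, r_outer = ro,
                  mu = mu)
  seeds <- data.frame(x = c(0.012, 0.018), y = 0, z = 0)
  ens <- advect(f, seeds, dt = 1e-4, T_total = 0.05)
  ens <- add_scalar_stress(ens)
  r <- sqrt(ens$x^2 + ens$y^2)
  B <- om * ri^2 * ro^2 / (ro^2 - ri^2)
  expect_equal(ens$sigma, 2 * mu * B / r^2, tolerance = 1e-6)
  # orbits stay on their radius
  r0 <- rep(sqrt(seeds$x^2 + seeds$y^2), times = length(unique(ens$t)))
  expect_equal(sort(r), sort(r0), tolerance = 1e-6)
})

test_that("log-normal moment matching reproduces the target moments exactly", {
  for (tgt in list(c(16.2, 14.4), c(3.5, 3.3), c(1, 2))) {
    p <- lognormal_match(tgt[1], tgt[2])
    expect_equal(exp(p["meanlog"] + p["sdlog"]^2 / 2), tgt[1],
                 ignore_attr = TRUE)
    ana_var <- (exp(p["sdlog"]^2) - 1) * exp(2 * p["meanlog"] + p["sdlog"]^2)
    expect_equal(sqrt(ana_var), tgt[2], ignore_attr = TRUE)
  }
  expect_error(lognormal_match(-1, 2), "positive")
})

test_that("preset SA populations converge to the printed footprint moments", {
  p <- device_preset("original")
  sa <- preset_sa_population(p, 20000, seed = 42)
  expect_lt(abs(mean(sa) - 16.2), 3 * 14.4 / sqrt(20000))
  expect_identical(preset_sa_population(p, 100, seed = 7),
                   preset_sa_population(p, 100, seed = 7))
})

test_that("preset ensembles carry constant stress and the preset footprint", {
  p <- device_preset("optimized")
  ens <- preset_ensemble(p, n = 1500, seed = 3)
  per_traj_sd <- ens |>
    dplyr::group_by(traj_id) |>
    dplyr::summarise(s = sd(sxy), .groups = "drop")
  expect_true(all(per_traj_sd$s == 0))
  pop <- sa_population(ens)
  expect_lt(abs(mean(pop$sa) - 3.5), 3 * 3.3 / sqrt(1500))
  # round-trips through the ensemble file format
  path <- withr::local_tempfile(fileext = ".csv")
  write_ensemble(ens[ens$traj_id %in% unique(ens$traj_id)[1:20], ], path)
  expect_equal(nrow(read_ensemble(path)), 20L * 5L)
})

test_that("hot-spot trajectories hit the preset peak-stress ranges", {
  for (i in 1:15) {
    orig <- hotspot_trajectory(device_preset("original"), seed = i)
    pk <- peak_stress(orig)$peak_scalar_stress
    expect_gte(pk, 200); expect_lte(pk, 600)
    opt <- hotspot_trajectory(device_preset("optimized"), seed = i)
    expect_lt(peak_stress(opt)$peak_scalar_stress, 200)
  }
  # SA agrees with the quadrature oracle on its own samples
  ht <- hotspot_trajectory(device_preset("original"), seed = 99)
  expect_equal(stress_accumulation(ht)$sa, sa_oracle(ht$t, ht$sxy))
})

test_that("synthetic PAS series are linear in expectation", {
  p <- device_preset("optimized")
  clean <- synth_pas(p, n_donors = 2, noise_sd = 0, seed = 1)
  expect_equal(suppressWarnings(fit_par(clean))$slope, p$par_slope,
               tolerance = 1e-12)
  expect_equal(sort(unique(clean$t_min)), c(0, 10, 20, 30))

  noisy <- synth_pas(p, n_donors = 400, noise_sd = 2e-4, seed = 2)
  by_t <- noisy |>
    dplyr::group_by(t_min) |>
    dplyr::summarise(m = mean(pas), .groups = "drop")
  expect_lt(max(abs(by_t$m - (0.01 + p$par_slope * by_t$t_min))),
            4 * 2e-4 / sqrt(400))
  expect_error(synth_pas(p, noise_sd = -1), "nonnegative")
})

test_that("rotor step angle follows rpm * 6 * dt", {
  expect_equal(rotor_step_angle(9500, 7.0e-5), 3.99)
  expect_equal(rotor_step_angle(60, 1), 360)
  expect_equal(rotor_step_angle(1234, 0), 0)
})
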