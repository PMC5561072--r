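# Monte Carlo rupture simulator: determinism, physical limits, and the
# first-passage oracle.

test_that("ensembles are reproducible and velocity substreams are independent", {
  cfg <- sim_config(velocities = c(100, 460), n_events_per_velocity = 20, seed = 3)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # inserting a velocity leaves the existing ones' events untouched
  cfg3 <- sim_config(velocities = c(100, 210, 460), n_events_per_velocity = 20, seed = 3)
  c3 <- run_simulation(cfg3)
  expect_identical(a$f_r, c3$f_r[c3$velocity %in% c(100, 460)])
})

test_that("single-event and boundary configurations behave", {
  cfg <- sim_config(velocities = 460, n_events_per_velocity = 1, seed = 1)
  ev <- run_simulation(cfg)
  expect_equal(nrow(ev), 1)
  expect_true(ev$f_r >= 0 && ev$r > 0 && ev$t_r > 0)
  # event loading rate is the analytic tether rate at the rupture force
  expect_equal(ev$r, loading_rate(ev$f_r, 460, 0.4, 150), tolerance = 1e-12)
})

test_that("force-free limit gives exponential rupture times", {
  set.seed(31)
  ev <- simulate_rupture(100, 0.4, 150, k_off = 1000, x_t = Inf,
                         dt = 1e-6, n_events = 2000)
  expect_equal(mean(ev$t_r), 1 / 1000, tolerance = 0.05)
})

test_that("mean rupture force increases with retraction velocity", {
  ev <- run_simulation(sim_config(n_events_per_velocity = 150, seed = 8))
  m <- tapply(ev$f_r, ev$velocity, mean)
  expect_true(all(diff(m[order(as.numeric(names(m)))]) > 0))
})

test_that("simulated forces follow the first-passage distribution", {
  d <- rupture_force_distribution(1000, 0.4, 150, 0.5, 0.3)
  expect_equal(max(d$cdf), 1, tolerance = 1e-3)
  # density normalisation by trapezoid
  area <- sum(0.5 * (d$density[-1] + d$density[-nrow(d)]) * diff(d$f))
  expect_equal(area, 1, tolerance = 1e-3)
  set.seed(7)
  ev <- simulate_rupture(1000, 0.4, 150, 0.5, 0.3, n_events = 2000)
  cdf <- approxfun(d$f, d$cdf, yleft = 0, yright = 1)
  D <- suppressWarnings(ks.test(ev$f_r, cdf)$statistic)
  expect_lt(unname(D), 0.05)
})

test_that("oracle mean approaches the constant-rate model deep in the kinetic regime", {
  # at R ~ 1e6 the tether's rate sweep is negligible across the narrow
  # rupture-force window and the two models agree to 2%
  d <- rupture_force_distribution(1e6, 0.4, 150, 0.5, 1.0)
  f0 <- attr(d, "mean_f")
  r0 <- loading_rate(f0, 1e6, 0.4, 150)
  expect_equal(mean_rupture_force(r0, 0, 1.0, 0.5), f0, tolerance = 0.02)
})

test_that("ensemble mean is insensitive to halving the time step", {
  set.seed(101)
  a <- simulate_rupture(1000, 0.4, 150, 0.5, 0.3, dt = 1e-6, n_events = 3000)
  set.seed(101)
  b <- simulate_rupture(1000, 0.4, 150, 0.5, 0.3, dt = 5e-7, n_events = 3000)
  expect_equal(mean(b$f_r), mean(a$f_r), tolerance = 0.01)
})

test_that("rupture data from different bonds collapse onto the tether curve", {
  e1 <- run_simulation(sim_config(velocities = c(100, 1000), n_events_per_velocity = 100,
                                  k_off = 0.5, x_t = 0.3, seed = 2))
  e2 <- run_simulation(sim_config(velocities = c(100, 1000), n_events_per_velocity = 100,
                                  k_off = 5, x_t = 0.6, seed = 3))
  both <- rbind(e1, e2)
  r_tether <- loading_rate(both$f_r, both$velocity, 0.4, 150)
  expect_equal(both$r, r_tether, tolerance = 1e-6)
  # yet the velocity-averaged spectra of the two bonds are far apart
  s1 <- build_spectrum(e1)
  s2 <- build_spectrum(e2)
  sep <- abs(s1$mean_f - s2$mean_f) / sqrt(s1$sem_f^2 + s2$sem_f^2)
  expect_true(all(sep > 3))
})

test_that("coarse time steps and unruptureable tethers are reported", {
  expect_warning(
    simulate_rupture(1000, 0.4, 150, k_off = 50, x_t = Inf, dt = 0.01,
                     n_events = 5),
    "probability"
  )
  expect_error(
    simulate_rupture(1e4, 0.4, 50, k_off = 1e-9, x_t = Inf, dt = 1e-5,
                     n_events = 1),
    "contour length"
  )
})

test_that("event CSV round-trips with its seed comment", {
  path <- withr::local_tempfile(fileext = ".csv")
  ev <- run_simulation(sim_config(velocities = 460, n_events_per_velocity = 10, seed = 4))
  write_events_csv(ev, path)
  expect_match(readLines(path, n = 1), "seed=4")
  back <- read_events_csv(path)
  expect_equal(back$f_r, ev$f_r)
  expect_equal(back$velocity, ev$velocity)
})
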