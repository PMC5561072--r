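# Rupture detection, last-event WLC fitting, numerical loading rate, and
# force-curve I/O.

test_that("force curves validate their invariants", {
  t <- seq(0.001, 0.02, by = 0.001)
  expect_error(force_curve(t[1:5], t[1:5], t[1:5], 100), "length")
  expect_error(force_curve(rev(t), t, t, 100), "increasing")
  expect_error(force_curve(t, rev(t), t, 100), "non-decreasing")
  expect_error(force_curve(t, t, t, -1), "velocity")
  cv <- force_curve(t, 100 * t, 0 * t, 100, curve_id = "a")
  expect_s3_class(cv, "force_curve")
})

test_that("curve CSV round-trips data and metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  cv <- make_wlc_curve(velocity = 500, x_rupture = 100)
  write_force_curve(cv, path)
  back <- read_force_curve(path)
  expect_equal(back$f, cv$f)
  expect_equal(attr(back, "velocity"), 500)
  expect_equal(attr(back, "temperature"), 293.15)
  expect_equal(attr(back, "curve_id"), "wlc_fixture")
})

test_that("rupture detection finds generated ruptures to within two samples", {
  cfg <- generator_config(n_prob = c(1, 0, 0, 0, 0), noise_sigma = 0,
                          baseline_drift = 0, L_cv = 0)
  set.seed(2)
  cv <- generate_curve(1000, cfg)
  tr <- attr(cv, "truth")
  det <- detect_last_rupture(cv)
  expect_true(det$detected)
  expect_lte(abs(det$index - tr$rupture_index), 2)
  # the pre-drop force is read off the running median, one sample's slope
  # below the instantaneous peak
  expect_equal(det$f_r, tr$f_r, tolerance = 0.01)

  cfgN <- generator_config(n_prob = c(1, 0, 0, 0, 0), noise_sigma = 5,
                           baseline_drift = 2, L_cv = 0.15)
  set.seed(4)
  for (i in 1:20) {
    cv <- generate_curve(1000, cfgN)
    tr <- attr(cv, "truth")
    det <- detect_last_rupture(cv)
    if (tr$f_r < 6 * 5) {
      # ruptures close to the 5-sigma drop threshold are legitimately lost
      next
    }
    expect_true(det$detected)
    expect_lte(abs(det$index - tr$rupture_index), 2)
    expect_lt(abs(det$f_r - tr$f_r), 3 * det$noise_sigma)
  }
})

test_that("flat curves yield no rupture and double ruptures yield the later one", {
  set.seed(5)
  t <- seq_len(500) * 1e-3
  flat <- force_curve(t, 100 * t, rnorm(500, 0, 5), 100)
  det <- detect_last_rupture(flat)
  expect_false(det$detected)
  expect_equal(det$reason, "no_rupture")

  f <- c(seq(0, 60, length.out = 200), seq(10, 40, length.out = 150),
         rep(0, 150))
  two <- force_curve(seq_along(f) * 1e-3, seq_along(f) * 0.1, f, 100)
  det2 <- detect_last_rupture(two, noise_sigma = 1)
  expect_true(det2$detected)
  expect_equal(det2$index, 350, tolerance = 2)
  expect_equal(det2$f_r, 40, tolerance = 3)
})

test_that("last-event WLC fits recover generating parameters", {
  cv <- make_wlc_curve(l_app = 0.4, L = 150, x_rupture = 120)
  det <- detect_last_rupture(cv)
  fit <- fit_last_event_wlc(cv, det$index, det$baseline, det$noise_sigma)
  expect_true(fit$converged)
  expect_equal(fit$l_app, 0.4, tolerance = 0.005)
  expect_equal(fit$L, 150, tolerance = 0.005)
})

test_that("noisy WLC fits recover the persistence length within 15%", {
  set.seed(12)
  l_hat <- replicate(100, {
    cv <- make_wlc_curve(l_app = 0.4, L = 150, velocity = 6000,
                         sample_rate = 1e4, x_rupture = 120, noise_sigma = 5)
    # ~200 samples in the loading segment
    fit <- fit_last_event_wlc(cv, ceiling(120 / 0.6), noise_sigma = 5)
    fit$l_app
  })
  expect_equal(median(l_hat, na.rm = TRUE), 0.4, tolerance = 0.15)
})

test_that("short fit windows are refused", {
  cv <- make_wlc_curve(x_rupture = 120)
  expect_error(fit_last_event_wlc(cv, 5), "window too short")
})

test_that("numerical loading rate is exact on a linear ramp and flags flats", {
  t <- seq_len(200) * 1e-3
  ramp <- force_curve(t, 100 * t, 250 * t, 100)
  expect_equal(numerical_loading_rate(ramp, 150), 250, tolerance = 1e-9)
  const <- force_curve(t, 100 * t, rep(30, 200), 100)
  expect_true(is.na(numerical_loading_rate(const, 150)))
  expect_error(numerical_loading_rate(ramp, 4), "at least 8")
})

test_that("a short slope window approaches the analytic loading rate", {
  cv <- make_wlc_curve(l_app = 0.4, L = 150, velocity = 1000, x_rupture = 120,
                       sample_rate = 1e5)
  det <- detect_last_rupture(cv)
  r_num <- numerical_loading_rate(cv, det$index, window_fraction = 0.002)
  r_ana <- loading_rate(det$f_r, 1000, 0.4, 150)
  expect_equal(r_num, r_ana, tolerance = 0.05)
})
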