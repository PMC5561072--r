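# Adhesion free energy per length and per-monomer binding free energy.

test_that("gamma_adh has the zero-force and strong-binding limits", {
  l_p <- 0.4
  b <- 2 * l_p
  expect_equal(gamma_adh(0, l_p), kBT() / b * log(4 * pi), tolerance = 1e-12)
  # strong binding: gamma/f_eq -> 1 as y grows. Expanding the exact form,
  # gamma b/kBT = y + ln(4 pi) - ln 2 - ln y + O(e^-2y), so the ratio
  # crosses 1 at y = 2 pi and approaches 1 from below thereafter.
  ratio <- function(y) {
    f <- y * kBT() / b
    gamma_adh(f, l_p) / f
  }
  expect_lte(abs(ratio(20) - 1), 0.15)
  expect_lt(abs(ratio(100) - 1), abs(ratio(20) - 1))
  expect_gt(ratio(5), 1)
  expect_lt(ratio(20), 1)
})

test_that("gamma_adh reproduces the hand-evaluated y = 2 point", {
  l_p <- 0.4
  b <- 2 * l_p
  f2 <- 2 * kBT() / b
  # ln(4 pi sinh(2)/2) = ln(4 pi * 1.8134302) = 3.1262444
  expect_equal(gamma_adh(f2, l_p), 3.1262444 * kBT() / b, tolerance = 1e-7)
  expect_equal(gamma_adh(f2, l_p), kBT() / b * log(4 * pi * sinh(2) / 2),
               tolerance = 1e-12)
})

test_that("gamma_adh is monotone, bounds f_eq from above, and is stable at large y", {
  l_p <- 0.4
  b <- 2 * l_p
  y <- seq(5, 100, length.out = 40)
  f <- y * kBT() / b
  g <- gamma_adh(f, l_p)
  expect_true(all(diff(g) > 0))
  # analytic bound on the excess: (gamma - f_eq) b / kBT <= ln(4 pi) + ln(1/y)
  excess <- (g - f) * b / kBT()
  expect_true(all(excess <= log(4 * pi) + log(1 / y) + 1e-9))
  # |ratio - 1| peaks near y = e^2.838 ~ 17 and shrinks steadily beyond
  ratio_dev <- abs(g / f - 1)
  past <- y > 20
  expect_true(all(diff(ratio_dev[past]) < 0))
  # no overflow far beyond double-precision exp range of sinh
  expect_true(is.finite(gamma_adh(5000, l_p)))
})

test_that("per-monomer free energy is gamma times the monomer length", {
  dg <- delta_G_bu(10 / 0.675, l_mono = 0.675)
  expect_equal(dg$dG_bu_pN_nm, 10)
  expect_equal(dg$dG_bu_kBT, 10 / kBT())
  expect_equal(delta_G_bu(0)$dG_bu_pN_nm, 0)
  # strong-binding arithmetic: f_eq = 10 pN at the default monomer
  expect_equal(10 * 0.675, 6.75)
  expect_equal(delta_G_bu(10)$dG_bu_kBT, 6.75 / kBT(), tolerance = 1e-12)
})

test_that("landscape summary assembles thermodynamics from a fit", {
  r <- 10^seq(1, 5, length.out = 8)
  sp <- tibble::tibble(mean_r = r, mean_f = mean_rupture_force(r, 20, 0.3, 0.5))
  fit <- fit_single_bond_model(sp)
  ls <- summarize_landscape(fit, l_p = 0.4, l_mono = 0.675)
  expect_s3_class(ls, "energy_landscape")
  expect_equal(ls$b, 0.8)
  expect_equal(ls$dG_bu_approx_pN_nm, 13.5, tolerance = 1e-3)
  expect_equal(ls$dG_bu_approx_pN_nm / kBT(), 3.336, tolerance = 1e-3)
  # exact form exceeds the approximation but, at y = 20 b/kBT ~ 4, not by much
  expect_gt(ls$dG_bu_pN_nm, ls$dG_bu_approx_pN_nm)
  expect_equal(ls$dG_bu_pN_nm, ls$gamma_adh * 0.675, tolerance = 1e-12)
  js <- jsonlite::fromJSON(landscape_json(ls))
  expect_equal(js$dG_bu_kBT, ls$dG_bu_kBT)
})

test_that("exact and approximate free energies converge in the strong-binding regime", {
  # the gap is (ln(4 pi / 2) - ln y) kBT / b: under 7% of gamma for y >= 10
  # and under 5% once y >= 60
  l_p <- 0.4
  y <- c(10, 20, 60, 200)
  f <- y * kBT() / (2 * l_p)
  rel <- abs(gamma_adh(f, l_p) - f) / gamma_adh(f, l_p)
  expect_true(all(rel < 0.07))
  expect_true(all(rel[y >= 60] < 0.05))
})

test_that("a zero-force fit still reports the finite exact free energy", {
  r <- 10^seq(2, 5, length.out = 6)
  sp <- tibble::tibble(mean_r = r, mean_f = mean_rupture_force(r, 0, 0.3, 0.5))
  fit <- fit_single_bond_model(sp)
  ls <- summarize_landscape(fit, l_p = 0.4)
  expect_equal(ls$dG_bu_approx_pN_nm, 0, tolerance = 0.01)
  expect_equal(ls$dG_bu_pN_nm, kBT() / 0.8 * log(4 * pi) * 0.675,
               tolerance = 1e-4)
})

test_that("non-converged fits are refused", {
  r <- 10^seq(1, 5, length.out = 8)
  sp <- tibble::tibble(mean_r = r, mean_f = mean_rupture_force(r, 20, 0.3, 0.5))
  fit <- fit_single_bond_model(sp)
  fit$converged <- FALSE
  expect_error(summarize_landscape(fit, l_p = 0.4), "non-converged")
})
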