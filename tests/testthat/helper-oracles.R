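# Independent numerical oracles and shared fixture parameters.

# E1 by adaptive quadrature of the substituted integrand
# E1(z) = e^{-z} * int_0^inf e^{-u} / (z + u) du
# (the substitution keeps the integrand well scaled at large z).
quad_E1 <- function(z) {
  vapply(z, function(zz) {
    exp(-zz) * stats::integrate(function(u) exp(-u) / (zz + u),
                                0, Inf, rel.tol = 1e-12)$value
  }, numeric(1))
}

# reference tether and bond used across tests (a ~150 nm polysaccharide
# pulled through a Bell bond of moderate strength)
ref_wlc <- list(l_app = 0.4, L = 150)
ref_bond <- list(k_off = 0.5, x_t = 0.3)

# single-segment WLC retraction curve built directly from the force law
# (independent of the package's stochastic generator): loading up to
# x_rupture, then a clean drop to baseline, plus optional noise.
make_wlc_curve <- function(l_app = 0.4, L = 150, velocity = 1000,
                           x_rupture = 120, sample_rate = 1e4,
                           noise_sigma = 0, n_tail = 200) {
  dt <- 1 / sample_rate
  k <- ceiling(x_rupture / (velocity * dt))
  n <- k + n_tail
  t <- seq_len(n) * dt
  x <- velocity * t
  f <- numeric(n)
  f[1:k] <- wlc_force(pmin(x[1:k], 0.999 * L), l_app, L)
  if (noise_sigma > 0) f <- f + rnorm(n, 0, noise_sigma)
  force_curve(t, x, f, velocity = velocity, curve_id = "wlc_fixture")
}
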