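# Worm-like-chain (WLC) force-extension mechanics in the interpolation form
#   f = (kBT / l_app) * [ x/L + 1/(4 (1 - x/L)^2) - 1/4 ]
# where l_app is the apparent persistence length of the loaded cluster and L
# the contour length. Units: nm, pN, s, K.

check_wlc <- function(l_app, L, temperature) {
  if (any(!is.finite(l_app)) || any(l_app <= 0)) {
    abort("`l_app` must be positive and finite (nm).")
  }
  if (any(!is.finite(L)) || any(L <= 0)) {
    abort("`L` must be positive and finite (nm).")
  }
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    abort("`temperature` must be positive (K).")
  }
  invisible(NULL)
}

check_extension <- function(x, L) {
  bad <- !is.finite(x) | x < 0 | x >= L
  if (any(bad)) {
    abort(sprintf(
      "extension out of the WLC domain [0, L): x = %g nm with L = %g nm",
      x[which(bad)[1]], max(L)
    ))
  }
  invisible(NULL)
}

#' Worm-like-chain force at a given extension
#'
#' Entropic-elasticity restoring force of a worm-like chain in the standard
#' interpolation form, parameterised by the apparent persistence length
#' `l_app` (for a cluster of N identical chains loaded in parallel,
#' `l_app = l_p / N`) and contour length `L`. The force is zero at zero
#' extension, strictly increasing, and diverges as the extension approaches
#' the contour length.
#'
#' @param x Tip-surface separation (extension) in nm; must satisfy
#'   `0 <= x < L`. Vectorised.
#' @param l_app Apparent persistence length in nm.
#' @param L Contour length in nm.
#' @param temperature Temperature in kelvin (default 293.15, i.e. 20 degC).
#' @return Force in pN.
#' @seealso [wlc_stiffness()], [loading_rate()], [wlc_inverse()]
#' @examples
#' wlc_force(75, l_app = 0.4, L = 150)
#' @export
wlc_force <- function(x, l_app, L, temperature = 293.15) {
  check_wlc(l_app, L, temperature)
  check_extension(x, L)
  s <- x / L
  (kBT(temperature) / l_app) * (s + 0.25 / (1 - s)^2 - 0.25)
}

#' Worm-like-chain stiffness (force gradient) at a given extension
#'
#' Analytic derivative df/dx of [wlc_force()]:
#' `(kBT/l_app) * (1/L + 1/(2 L (1 - x/L)^3))`. Positive everywhere and
#' stiffening toward full extension; used to convert retraction velocity into
#' the instantaneous loading rate.
#'
#' @inheritParams wlc_force
#' @return Stiffness in pN/nm.
#' @export
wlc_stiffness <- function(x, l_app, L, temperature = 293.15) {
  check_wlc(l_app, L, temperature)
  check_extension(x, L)
  s <- x / L
  (kBT(temperature) / l_app) * (1 / L + 1 / (2 * L * (1 - s)^3))
}

#' Invert the worm-like-chain force law
#'
#' Finds the extension `x` at which [wlc_force()] equals a target force, by
#' bisection on `[0, (1 - 1e-12) L]` to an absolute tolerance of `1e-10 * L`.
#' The force law is strictly monotone so the bracket always converges.
#'
#' @param f Target force in pN, `f >= 0`. Vectorised.
#' @inheritParams wlc_force
#' @return Extension in nm.
#' @export
wlc_inverse <- function(f, l_app, L, temperature = 293.15) {
  check_wlc(l_app, L, temperature)
  if (any(!is.finite(f)) || any(f < 0)) {
    abort("`f` must be non-negative and finite (pN).")
  }
  scale <- kBT(temperature) / l_app
  fmax <- scale * (1 - 1e-12 + 0.25 / 1e-24 - 0.25)
  if (any(f >= fmax)) {
    abort(sprintf(
      "WLC inversion failed: force %g pN unreachable below full extension (l_app = %g nm, L = %g nm)",
      max(f), l_app, L
    ))
  }
  lo <- rep(0, length(f))
  hi <- rep((1 - 1e-12) * L, length(f))
  # 60 halvings take the bracket width below 1e-10 * L from L.
  for (i in seq_len(60)) {
    mid <- 0.5 * (lo + hi)
    s <- mid / L
    fm <- scale * (s + 0.25 / (1 - s)^2 - 0.25)
    below <- fm < f
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  0.5 * (lo + hi)
}

#' Instantaneous loading rate of a bond pulled through a polymer tether
#'
#' For a tether retracted at constant velocity `v`, the loading rate on the
#' bond is `r = dF/dt = v * df/dx` evaluated at the extension where the chain
#' carries force `f`. Unlike a stiff cantilever, the polymer sweeps the bond
#' over a continuum of loading rates, so `r` depends on the force at which
#' rupture happened. The (f, r) relation is set entirely by the tether and
#' velocity, never by the bond: rupture data from any bond pulled through the
#' same linker fall on this one curve.
#'
#' @param f Force at which the rate is evaluated, pN. Vectorised.
#' @param v Retraction velocity in nm/s, `v > 0`.
#' @inheritParams wlc_force
#' @return Loading rate in pN/s.
#' @export
loading_rate <- function(f, v, l_app, L, temperature = 293.15) {
  if (any(!is.finite(v)) || any(v <= 0)) {
    abort("`v` must be positive and finite (nm/s).")
  }
  x <- wlc_inverse(f, l_app, L, temperature)
  v * wlc_stiffness(x, l_app, L, temperature)
}

#' Number of chains loaded in parallel
#'
#' The apparent persistence length of a cluster of N identical chains sharing
#' the load is `l_p / N`, so `N = l_p / l_app`. Non-integer values are
#' returned as-is; interpreting them (and discarding multi-chain events) is
#' the job of [filter_events()].
#'
#' @param l_app Apparent persistence length fitted to a rupture event, nm.
#' @param l_p Single-polymer persistence length, nm.
#' @return Estimated chain count (real-valued).
#' @export
estimate_N <- function(l_app, l_p) {
  if (any(!is.finite(l_app)) || any(l_app <= 0)) {
    abort("`l_app` must be positive (nm).")
  }
  if (any(!is.finite(l_p)) || any(l_p <= 0)) {
    abort("`l_p` must be positive (nm).")
  }
  l_p / l_app
}
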