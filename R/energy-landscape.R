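# From the fitted equilibrium force to binding thermodynamics: the adhesion
# free energy per unit polymer length,
#   gamma_adh = (kBT / b) ln(4 pi sinh(y) / y),  y = f_eq b / kBT,  b = 2 l_p
# and the per-monomer binding free energy dG_bu = gamma_adh * l_mono
# (approximately f_eq * l_mono deep in the strong-binding regime y >> 1).

log_sinh_over_y <- function(y) {
  out <- numeric(length(y))
  small <- y < 1e-4
  mid <- !small & y < 30
  big <- y >= 30
  # sinh(y)/y = 1 + y^2/6 + O(y^4)
  out[small] <- y[small]^2 / 6
  out[mid] <- log(sinh(y[mid]) / y[mid])
  # ln sinh y = y - ln 2 + ln(1 - e^{-2y}), stable for large y
  out[big] <- y[big] - log(2) + log1p(-exp(-2 * y[big])) - log(y[big])
  out
}

#' Adhesion free energy per unit polymer length
#'
#' At equilibrium, the force needed to peel a polymer off a surface relates
#' to the adhesion free energy per unit length through
#' `gamma_adh = (kBT / b) * ln(4 pi sinh(y) / y)` with
#' `y = f_eq * b / kBT` and Kuhn length `b = 2 l_p`. When `y >> 1` this
#' reduces to `gamma_adh ~ f_eq`; at `f_eq = 0` it takes the finite value
#' `(kBT / b) ln(4 pi)`. Large `y` is handled through the log-domain form of
#' `sinh`, small `y` through its series, so the whole range is stable.
#'
#' @param f_eq Equilibrium force, pN (`>= 0`). Vectorised.
#' @param l_p Single-polymer persistence length, nm.
#' @param temperature Kelvin.
#' @return Adhesion free energy per length, pN (= pN nm / nm).
#' @export
gamma_adh <- function(f_eq, l_p, temperature = 293.15) {
  if (any(!is.finite(f_eq)) || any(f_eq < 0)) {
    abort("`f_eq` must be non-negative and finite (pN).")
  }
  if (any(!is.finite(l_p)) || any(l_p <= 0)) {
    abort("`l_p` must be positive (nm).")
  }
  b <- 2 * l_p
  kT <- kBT(temperature)
  y <- f_eq * b / kT
  (kT / b) * (log(4 * pi) + log_sinh_over_y(y))
}

#' Binding free energy per monomer
#'
#' `dG_bu = gamma_adh * l_mono`: the free-energy gain of moving one monomer
#' from solution onto the surface. Reported in pN nm and in units of kBT.
#'
#' @param gamma Adhesion free energy per length, pN (from [gamma_adh()]).
#' @param l_mono Monomer length, nm. The default 0.675 nm is a saccharide
#'   ring (0.483 nm) plus the bonded carboxyl group (0.192 nm).
#' @param temperature Kelvin.
#' @return A tibble with columns `dG_bu_pN_nm` and `dG_bu_kBT`.
#' @export
delta_G_bu <- function(gamma, l_mono = l_mono_default(), temperature = 293.15) {
  if (any(!is.finite(gamma)) || any(gamma < 0)) {
    abort("`gamma` must be non-negative (pN).")
  }
  if (l_mono <= 0) abort("`l_mono` must be positive (nm).")
  dG <- gamma * l_mono
  tibble(dG_bu_pN_nm = dG, dG_bu_kBT = dG / kBT(temperature))
}

#' Assemble the energy-landscape summary from a single-bond fit
#'
#' Combines the fitted kinetic parameters (`x_t`, `k_off`) with the
#' thermodynamics derived from `f_eq`: the adhesion free energy per length
#' (exact expression) and the per-monomer binding free energy, both exact
#' (`gamma_adh * l_mono`) and in the strong-binding approximation
#' (`f_eq * l_mono`), with their relative difference. Uncertainty on
#' `dG_bu` is propagated from the fit's `f_eq` standard error by the delta
#' method through the exact expression.
#'
#' @param fit A converged `bond_fit` from [fit_single_bond_model()].
#' @param l_p Single-polymer persistence length, nm.
#' @param l_mono Monomer length, nm (default 0.675).
#' @return A one-row tibble of class `energy_landscape` with columns
#'   `f_eq`, `x_t`, `k_off`, `f_beta`, `b`, `l_mono`, `gamma_adh`,
#'   `dG_bu_pN_nm`, `dG_bu_kBT`, `dG_bu_approx_pN_nm`, `approx_rel_diff`,
#'   `dG_bu_se_pN_nm`.
#' @export
summarize_landscape <- function(fit, l_p, l_mono = l_mono_default()) {
  stopifnot(inherits(fit, "bond_fit"))
  if (!isTRUE(fit$converged)) {
    abort("refusing to summarise a non-converged single-bond fit.")
  }
  if (l_p <= 0) abort("`l_p` must be positive (nm).")
  f_eq <- unname(fit$params["f_eq"])
  temperature <- fit$temperature
  g <- gamma_adh(f_eq, l_p, temperature)
  dG <- delta_G_bu(g, l_mono, temperature)
  dG_approx <- f_eq * l_mono
  # delta method: d gamma / d f_eq by central difference at the estimate
  h <- max(1e-6, 1e-6 * max(f_eq, 1))
  dg_df <- (gamma_adh(f_eq + h, l_p, temperature) -
              gamma_adh(max(f_eq - h, 0), l_p, temperature)) /
    (h + min(h, f_eq))
  dG_se <- abs(dg_df) * unname(fit$se["f_eq"]) * l_mono
  out <- tibble(
    f_eq = f_eq,
    x_t = unname(fit$params["x_t"]),
    k_off = unname(fit$params["k_off"]),
    f_beta = fit$f_beta,
    b = 2 * l_p,
    l_mono = l_mono,
    gamma_adh = g,
    dG_bu_pN_nm = dG$dG_bu_pN_nm,
    dG_bu_kBT = dG$dG_bu_kBT,
    dG_bu_approx_pN_nm = dG_approx,
    approx_rel_diff = ifelse(dG$dG_bu_pN_nm > 0,
                             abs(dG$dG_bu_pN_nm - dG_approx) / dG$dG_bu_pN_nm,
                             NA_real_),
    dG_bu_se_pN_nm = dG_se
  )
  class(out) <- c("energy_landscape", class(out))
  attr(out, "fit") <- fit
  out
}

#' Serialise an energy-landscape summary to JSON
#'
#' @param x An `energy_landscape` from [summarize_landscape()].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written).
#' @export
landscape_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "energy_landscape"))
  fit <- attr(x, "fit")
  obj <- list(
    f_eq_pN = x$f_eq, x_t_nm = x$x_t, k_off_per_s = x$k_off,
    gamma_adh_pN = x$gamma_adh,
    dG_bu_pN_nm = x$dG_bu_pN_nm, dG_bu_kBT = x$dG_bu_kBT,
    l_mono_nm = x$l_mono, b_nm = x$b, method = "exact",
    dG_bu_approx_pN_nm = x$dG_bu_approx_pN_nm,
    ci95 = if (!is.null(fit)) list(
      f_eq_pN = unname(fit$ci95["f_eq", ]),
      x_t_nm = unname(fit$ci95["x_t", ]),
      k_off_per_s = unname(fit$ci95["k_off", ])
    )
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
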