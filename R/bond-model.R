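# Bell-Evans unbinding kinetics and the single-bond mean-rupture-force model
#
#   <f>(r) = f_eq + f_beta * exp(1/R) * E1(1/R),   R = r / (k_u(f_eq) f_beta)
#   k_u(f) = k_off * exp(f / f_beta),              f_beta = kBT / x_t
#
# As r -> 0 the mean force plateaus at the equilibrium force f_eq; at fast
# loading it grows like f_beta * (ln R - gamma), the familiar force vs
# log-loading-rate regime carrying x_t and k_off.

#' Force-dependent Bell unbinding rate
#'
#' `k_u(f) = k_off * exp(f * x_t / kBT)`: the intrinsic unbinding rate
#' accelerated exponentially by the applied force, with slope set by the
#' distance to the transition state `x_t` (equivalently the thermal force
#' scale `f_beta = kBT / x_t`). `x_t = Inf` is accepted and gives the
#' force-independent rate `k_off`, the limit used to validate the simulator
#' against a plain exponential first-passage time.
#'
#' @param f Applied force in pN, `f >= 0`. Vectorised.
#' @param k_off Intrinsic (zero-force) unbinding rate, 1/s.
#' @param x_t Distance to the transition state, nm (may be `Inf`).
#' @param temperature Temperature in kelvin.
#' @return Unbinding rate in 1/s.
#' @export
bell_rate <- function(f, k_off, x_t, temperature = 293.15) {
  if (any(!is.finite(k_off)) || any(k_off <= 0)) {
    abort("`k_off` must be positive and finite (1/s).")
  }
  if (any(is.na(x_t)) || any(x_t <= 0)) {
    abort("`x_t` must be positive (nm).")
  }
  if (any(!is.finite(f)) || any(f < 0)) {
    abort("`f` must be non-negative and finite (pN).")
  }
  if (is.infinite(x_t)) {
    return(rep(k_off, length(f)))
  }
  z <- f * x_t / kBT(temperature)
  if (any(z > 700)) {
    abort(sprintf(
      "Bell rate overflow: f * x_t / kBT = %g exceeds 700; the rate is no longer representable",
      max(z)
    ))
  }
  k_off * exp(z)
}

#' Mean rupture force of a single bond at a given loading rate
#'
#' The mean first-rupture force of a reversible single bond loaded at
#' constant rate `r`:
#' `<f> = f_eq + f_beta * exp(1/R) E1(1/R)` with
#' `R = r / (k_u(f_eq) * f_beta)`. The expression interpolates between the
#' near-equilibrium plateau (`<f> -> f_eq` as `r -> 0`) and the kinetic
#' regime (`<f> ~ f_eq + f_beta (ln R - gamma_Euler)` at fast loading). The
#' kernel `exp(x) E1(x)` is evaluated in scaled form ([exp1_scaled()]) so
#' extreme `R` never overflows.
#'
#' @param r Loading rate in pN/s, `r > 0`. Vectorised.
#' @param f_eq Equilibrium force in pN, `>= 0`.
#' @param x_t Distance to the transition state, nm.
#' @param k_off Intrinsic unbinding rate, 1/s.
#' @param temperature Temperature in kelvin.
#' @return Mean rupture force in pN.
#' @examples
#' mean_rupture_force(10^(1:5), f_eq = 20, x_t = 0.3, k_off = 0.5)
#' @export
mean_rupture_force <- function(r, f_eq, x_t, k_off, temperature = 293.15) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    abort("`r` must be positive and finite (pN/s).")
  }
  if (any(!is.finite(f_eq)) || any(f_eq < 0)) {
    abort("`f_eq` must be non-negative (pN).")
  }
  f_beta <- kBT(temperature) / x_t
  R <- r / (bell_rate(f_eq, k_off, x_t, temperature) * f_beta)
  f_eq + f_beta * exp1_scaled(1 / R)
}

#' Fit the single-bond model to a velocity-averaged mean-force spectrum
#'
#' Weighted nonlinear least squares of [mean_rupture_force()] against a
#' spectrum of (mean loading rate, mean rupture force) points, one per
#' retraction velocity (see [build_spectrum()]). Returns the three bond
#' parameters: equilibrium force `f_eq`, transition-state distance `x_t`,
#' and intrinsic unbinding rate `k_off`.
#'
#' The model is stiff in `k_off`, so the optimiser is multi-started:
#' `f_eq` from the smallest mean force, `x_t` from `kBT / slope` of force vs
#' `ln r` over the upper half of the rates, and `k_off` over a decade grid
#' `1e-3 ... 10` 1/s. Each start runs Levenberg-Marquardt on
#' `(f_eq, ln x_t, ln k_off)` (the logs enforce positivity); the best
#' converged start wins. Points are weighted by `1 / sem_f^2` when a finite,
#' positive `sem_f` column is present, otherwise equally.
#'
#' @param spectrum Data frame with columns `mean_r` (pN/s), `mean_f` (pN) and
#'   optionally `sem_f` (pN) and `n_events`. At least 4 points are required;
#'   a span of under 1.5 decades in `mean_r` triggers a warning because the
#'   kinetic slope is then poorly constrained.
#' @param temperature Temperature in kelvin.
#' @param init Optional named list or vector with starting values `f_eq`,
#'   `x_t`, `k_off`; replaces the multi-start grid.
#' @param weights `"sem"` (default; inverse-variance when `sem_f` is usable)
#'   or `"none"`.
#' @param n_boot Number of bootstrap resamples of the spectrum points for
#'   uncertainty estimation; `0` (default) uses the Jacobian-based covariance
#'   at the optimum instead.
#' @return An object of class `bond_fit`: access parameters with
#'   [tidy()], fit diagnostics with [glance()], and plot data plus fit with
#'   [autoplot()]. Fields include `params` (named vector), `ci95`, `vcov`,
#'   `residual_norm`, `n_points`, `spectrum`.
#' @export
fit_single_bond_model <- function(spectrum, temperature = 293.15, init = NULL,
                                  weights = c("sem", "none"), n_boot = 0) {
  weights <- match.arg(weights)
  spectrum <- as_tibble(spectrum)
  if (!all(c("mean_r", "mean_f") %in% names(spectrum))) {
    abort("`spectrum` needs columns `mean_r` and `mean_f`.")
  }
  spectrum <- arrange(spectrum, .data$mean_r)
  r <- spectrum$mean_r
  f <- spectrum$mean_f
  if (any(!is.finite(r)) || any(r <= 0) || any(!is.finite(f))) {
    abort("spectrum points must have finite mean_f and positive mean_r.")
  }
  n <- length(r)
  if (n < 4) {
    abort(sprintf("single-bond fit needs at least 4 spectrum points, got %d (3 free parameters).", n))
  }
  if (log10(max(r) / min(r)) < 1.5) {
    warn("mean loading rates span less than 1.5 decades; x_t and k_off may be poorly constrained.")
  }
  w <- rep(1, n)
  if (weights == "sem" && "sem_f" %in% names(spectrum)) {
    sem <- spectrum$sem_f
    if (all(is.finite(sem)) && all(sem > 0)) w <- 1 / sem^2
  }
  sw <- sqrt(w)
  kT <- kBT(temperature)

  # residuals over theta = (f_eq, log x_t, log k_off)
  resid_fn <- function(theta) {
    fe <- theta[1]
    xt <- exp(theta[2])
    ko <- exp(theta[3])
    z <- fe * xt / kT
    if (fe < 0 || z > 650) {
      return(rep(1e6, n))
    }
    pred <- tryCatch(
      mean_rupture_force(r, fe, xt, ko, temperature),
      error = function(e) rep(NA_real_, n)
    )
    if (any(!is.finite(pred))) {
      return(rep(1e6, n))
    }
    sw * (f - pred)
  }

  starts <- list()
  if (!is.null(init)) {
    init <- as.list(init)
    starts[[1]] <- c(init$f_eq, log(init$x_t), log(init$k_off))
  } else {
    f_eq0 <- max(min(f), 0)
    upper <- r >= sqrt(min(r) * max(r))
    if (sum(upper) < 2) upper <- rep(TRUE, n)
    slope <- coef(lm(f[upper] ~ log(r[upper])))[2]
    x_t0 <- if (is.finite(slope) && slope > 0) kT / slope else 0.3
    x_t0 <- min(max(x_t0, 1e-3), 50)
    for (k_off0 in 10^seq(-3, 1, by = 1)) {
      starts[[length(starts) + 1L]] <- c(f_eq0, log(x_t0), log(k_off0))
      starts[[length(starts) + 1L]] <- c(0.5 * f_eq0, log(x_t0), log(k_off0))
    }
  }

  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = th0, fn = resid_fn,
        lower = c(0, log(1e-4), log(1e-10)),
        upper = c(max(f), log(1e3), log(1e8)),
        control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-14, ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    abort("single-bond fit failed to converge from any start.")
  }

  theta <- best$par
  params <- c(f_eq = theta[1], x_t = exp(theta[2]), k_off = exp(theta[3]))
  dof <- max(n - 3, 1)
  sigma2 <- best$deviance / dof
  vcov_theta <- tryCatch(sigma2 * solve(best$hessian), error = function(e) {
    matrix(NA_real_, 3, 3)
  })
  # delta method: d x_t / d log x_t = x_t etc.
  grad <- diag(c(1, params["x_t"], params["k_off"]))
  vcov_p <- grad %*% vcov_theta %*% grad
  dimnames(vcov_p) <- list(names(params), names(params))
  se <- sqrt(pmax(diag(vcov_p), 0))

  if (n_boot > 0) {
    boot <- matrix(NA_real_, n_boot, 3)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      rb <- r[idx]; fb <- f[idx]; swb <- sw[idx]
      fnb <- function(theta) {
        pred <- tryCatch(
          mean_rupture_force(rb, theta[1], exp(theta[2]), exp(theta[3]), temperature),
          error = function(e) rep(NA_real_, n)
        )
        if (theta[1] < 0 || any(!is.finite(pred))) return(rep(1e6, n))
        swb * (fb - pred)
      }
      fitb <- tryCatch(
        minpack.lm::nls.lm(par = theta, fn = fnb,
                           lower = c(0, log(1e-4), log(1e-10)),
                           upper = c(max(f), log(1e3), log(1e8))),
        error = function(e) NULL
      )
      if (!is.null(fitb)) {
        boot[b, ] <- c(fitb$par[1], exp(fitb$par[2]), exp(fitb$par[3]))
      }
    }
    se <- apply(boot, 2, sd, na.rm = TRUE)
  }
  names(se) <- names(params)
  ci95 <- cbind(lower = params - 1.96 * se, upper = params + 1.96 * se)
  ci95[, "lower"] <- pmax(ci95[, "lower"], c(0, 0, 0))

  structure(
    list(
      params = params,
      se = se,
      ci95 = ci95,
      vcov = vcov_p,
      f_beta = unname(kT / params["x_t"]),
      residual_norm = sqrt(best$deviance),
      n_points = n,
      temperature = temperature,
      weights = if (all(w == 1)) "none" else "sem",
      converged = best$info %in% 1:4,
      spectrum = spectrum
    ),
    class = "bond_fit"
  )
}

#' @export
print.bond_fit <- function(x, ...) {
  cat("Single-bond model fit (", x$n_points, " spectrum points)\n", sep = "")
  cat(sprintf("  f_eq  = %8.3f pN   (se %.3f)\n", x$params["f_eq"], x$se["f_eq"]))
  cat(sprintf("  x_t   = %8.4f nm   (se %.4f)   f_beta = %.2f pN\n",
              x$params["x_t"], x$se["x_t"], x$f_beta))
  cat(sprintf("  k_off = %8.4g 1/s  (se %.3g)\n", x$params["k_off"], x$se["k_off"]))
  cat(sprintf("  residual norm %.4g, weights: %s\n", x$residual_norm, x$weights))
  invisible(x)
}

#' Tidy a single-bond fit into one row per parameter
#'
#' @param x A `bond_fit` from [fit_single_bond_model()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy bond_fit
#' @export
tidy.bond_fit <- function(x, ...) {
  tibble(
    term = names(x$params),
    estimate = unname(x$params),
    std.error = unname(x$se),
    conf.low = unname(x$ci95[, "lower"]),
    conf.high = unname(x$ci95[, "upper"])
  )
}

#' One-row summary of a single-bond fit
#'
#' @inheritParams tidy.bond_fit
#' @return A tibble with `f_eq`, `x_t`, `k_off`, `f_beta`, `residual_norm`,
#'   `n_points`, `converged`.
#' @method glance bond_fit
#' @export
glance.bond_fit <- function(x, ...) {
  tibble(
    f_eq = unname(x$params["f_eq"]),
    x_t = unname(x$params["x_t"]),
    k_off = unname(x$params["k_off"]),
    f_beta = x$f_beta,
    residual_norm = x$residual_norm,
    n_points = x$n_points,
    converged = x$converged
  )
}

#' Serialise a single-bond fit to JSON
#'
#' @param x A `bond_fit`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
bond_fit_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "bond_fit"))
  obj <- list(
    f_eq_pN = unname(x$params["f_eq"]),
    x_t_nm = unname(x$params["x_t"]),
    k_off_per_s = unname(x$params["k_off"]),
    ci95 = list(
      f_eq_pN = unname(x$ci95["f_eq", ]),
      x_t_nm = unname(x$ci95["x_t", ]),
      k_off_per_s = unname(x$ci95["k_off", ])
    ),
    residual = x$residual_norm,
    n_points = x$n_points
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
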