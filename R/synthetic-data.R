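# Ground-truthed synthetic force curves emulating a polymer-linked DFS
# experiment: an unknown number of WLC tethers attached in parallel, each
# rupturing stochastically under the Bell rate along the retraction
# trajectory, with Gaussian force noise and a linear baseline drift. Every
# curve carries a truth record, so each pipeline stage can be validated
# without instrument data.

#' Synthetic-dataset configuration
#'
#' Defaults emulate the acquisition protocol: seven retraction speeds
#' log-spaced from 5 nm/s to 10 um/s, 100 curves per speed collected in
#' interleaved blocks of five (at least 700 curves per experiment). Chains
#' attach in a random number N (1-5); a cluster of N equal chains has
#' apparent persistence length `l_p / N`, which is what the
#' persistence-length filter exploits downstream.
#'
#' @param velocities Retraction speeds, nm/s.
#' @param curves_per_velocity Curves per speed (default 100).
#' @param n_prob Probability of N = 1..5 attached chains per curve.
#' @param l_p Single-polymer persistence length, nm (default 0.4, a typical
#'   polysaccharide scale).
#' @param L_mean,L_cv Contour length distribution: log-normal with this mean
#'   (nm) and coefficient of variation.
#' @param k_off,x_t Bell bond parameters per attachment (1/s, nm).
#' @param noise_sigma Gaussian force noise SD, pN (default 5).
#' @param sample_rate Sampling rate, Hz (default 1e4).
#' @param baseline_drift Linear force drift over the curve, pN (default 2).
#' @param temperature Kelvin.
#' @param seed Integer seed for [generate_dataset()] / [generate_ensemble()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(velocities = round(5 * (10000 / 5)^(0:6 / 6), 1),
                             curves_per_velocity = 100,
                             n_prob = c(0.45, 0.25, 0.15, 0.1, 0.05),
                             l_p = 0.4, L_mean = 150, L_cv = 0.15,
                             k_off = 0.5, x_t = 0.3,
                             noise_sigma = 5, sample_rate = 1e4,
                             baseline_drift = 2,
                             temperature = 293.15, seed = 1L) {
  if (any(velocities <= 0)) abort("all `velocities` must be positive (nm/s).")
  if (curves_per_velocity < 1) abort("`curves_per_velocity` must be >= 1.")
  if (any(n_prob < 0) || abs(sum(n_prob) - 1) > 1e-8) {
    abort("`n_prob` must be non-negative and sum to 1.")
  }
  if (l_p <= 0 || L_mean <= 0 || L_cv < 0) abort("lengths must be positive.")
  if (k_off <= 0 || x_t <= 0) abort("bond parameters must be positive.")
  if (noise_sigma < 0 || sample_rate <= 0) {
    abort("`noise_sigma` must be >= 0 and `sample_rate` positive.")
  }
  structure(
    list(velocities = velocities,
         curves_per_velocity = as.integer(curves_per_velocity),
         n_prob = n_prob / sum(n_prob), l_p = l_p,
         L_mean = L_mean, L_cv = L_cv, k_off = k_off, x_t = x_t,
         noise_sigma = noise_sigma, sample_rate = sample_rate,
         baseline_drift = baseline_drift, temperature = temperature,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Rupture sample index of one chain along x = v t: inverse-CDF sampling of
# the cumulative Bell hazard (exponential clock E), chunked so slow curves
# do not allocate the full trajectory up front. Returns the first sample
# at which the integrated hazard exceeds E (capped at 0.999 L where the
# diverging force makes rupture certain).
chain_rupture_index <- function(L, E, velocity, cfg, chunk = 50000L) {
  dt <- 1 / cfg$sample_rate
  f_beta <- kBT(cfg$temperature) / cfg$x_t
  x_cap <- 0.999 * L
  cumhaz <- 0
  offset <- 0L
  repeat {
    idx <- offset + seq_len(chunk)
    x <- pmin(velocity * idx * dt, x_cap)
    f <- wlc_force(x, cfg$l_p, L, cfg$temperature)
    k <- cfg$k_off * exp(pmin(f / f_beta, 700))
    ch <- cumhaz + cumsum(k * dt)
    hit <- which(ch >= E)
    if (length(hit)) return(offset + hit[1])
    if (x[chunk] >= x_cap) return(offset + chunk) # hazard saturated: force rupture
    cumhaz <- ch[chunk]
    offset <- offset + chunk
  }
}

#' Generate one synthetic force curve with ground truth
#'
#' Draws N attached chains (each with its own contour length), lets each
#' rupture independently under the Bell rate integrated along the shared
#' retraction trajectory, sums the attached chains' WLC forces, and adds
#' Gaussian noise plus a linear baseline drift. The post-rupture tail
#' (about 20% of the curve) is retained so baseline and noise can be
#' re-estimated by the detector. Uses the current RNG state; seed the
#' stream (or use [generate_ensemble()] / [generate_dataset()]) for
#' reproducibility.
#'
#' @param velocity Retraction speed, nm/s.
#' @param cfg A [generator_config()].
#' @param curve_id Identifier for the curve.
#' @return A [force_curve()] with attribute `truth`: a list with `N`,
#'   per-chain `L`, rupture times `t_r` and chain forces `f_r`, and the
#'   last (single-chain) event's `l_app`, `L`, `f_r`, `t_r` and analytic
#'   loading rate `r`.
#' @export
generate_curve <- function(velocity, cfg = generator_config(),
                           curve_id = "curve") {
  stopifnot(inherits(cfg, "generator_config"))
  dt <- 1 / cfg$sample_rate
  N <- sample.int(length(cfg$n_prob), 1, prob = cfg$n_prob)
  sdlog <- sqrt(log(1 + cfg$L_cv^2))
  L <- stats::rlnorm(N, meanlog = log(cfg$L_mean) - sdlog^2 / 2, sdlog = sdlog)
  E <- rexp(N)
  idx_r <- vapply(seq_len(N), function(i) {
    chain_rupture_index(L[i], E[i], velocity, cfg)
  }, integer(1))
  last_chain <- which.max(idx_r)
  n_pre <- max(idx_r)
  n_tail <- max(50L, ceiling(0.25 * n_pre))
  n <- max(n_pre + n_tail, 16L)
  t <- seq_len(n) * dt
  x <- velocity * t
  f <- numeric(n)
  for (i in seq_len(N)) {
    live <- seq_len(idx_r[i])
    xi <- pmin(x[live], 0.999 * L[i])
    f[live] <- f[live] + wlc_force(xi, cfg$l_p, L[i], cfg$temperature)
  }
  f_chain <- vapply(seq_len(N), function(i) {
    wlc_force(pmin(x[idx_r[i]], 0.999 * L[i]), cfg$l_p, L[i], cfg$temperature)
  }, numeric(1))
  drift <- cfg$baseline_drift * t / t[n]
  noise <- if (cfg$noise_sigma > 0) rnorm(n, 0, cfg$noise_sigma) else 0
  curve <- force_curve(t, x, f + drift + noise,
                       velocity = velocity, temperature = cfg$temperature,
                       curve_id = curve_id)
  f_r_last <- f_chain[last_chain]
  attr(curve, "truth") <- list(
    N = N,
    chains = tibble(L = L, t_r = t[idx_r], f_r = f_chain),
    rupture_index = n_pre,
    l_app = cfg$l_p,
    L = L[last_chain],
    f_r = f_r_last,
    t_r = t[n_pre],
    r = loading_rate(f_r_last, velocity, cfg$l_p, L[last_chain],
                     cfg$temperature)
  )
  curve
}

generator_schedule <- function(cfg, block = 5L) {
  # interleave speeds in blocks of `block` curves, cycling until each speed
  # has its full count (the acquisition schedule that averages out local
  # surface heterogeneity)
  per_v <- cfg$curves_per_velocity
  cycles <- ceiling(per_v / block)
  v_seq <- unlist(lapply(seq_len(cycles), function(cy) {
    take <- min(block, per_v - (cy - 1L) * block)
    rep(cfg$velocities, each = take)
  }))
  v_seq
}

#' Generate an in-memory synthetic ensemble
#'
#' Like [generate_dataset()] but without touching disk: returns the curves
#' and a truth manifest tibble.
#'
#' @param cfg A [generator_config()].
#' @return A list with `curves` (list of [force_curve()]) and `truth`
#'   (tibble: `curve_id`, `velocity`, `N`, `l_app`, `L`, `f_r`, `t_r`, `r`
#'   for the last event of each curve).
#' @export
generate_ensemble <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  v_seq <- generator_schedule(cfg)
  ids <- sprintf("curve_%04d", seq_along(v_seq))
  curves <- purrr::map2(v_seq, ids, function(v, id) {
    generate_curve(v, cfg, curve_id = id)
  })
  truth <- purrr::map2(curves, ids, function(curve, id) {
    tr <- attr(curve, "truth")
    tibble(curve_id = id, velocity = curve_velocity(curve), N = tr$N,
           l_app = tr$l_app, L = tr$L, f_r = tr$f_r, t_r = tr$t_r, r = tr$r)
  }) |> bind_rows()
  list(curves = curves, truth = truth)
}

#' Write a synthetic dataset to a directory
#'
#' Writes one commented-CSV file per curve (the same format
#' [read_curve_dataset()] consumes), interleaving retraction speeds in
#' blocks of five per the acquisition schedule, plus a `manifest.json`
#' truth record keyed by curve id.
#'
#' @param cfg A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a tibble with `curve_id`, `file`, `velocity`;
#'   the truth manifest path is in `attr(, "manifest")`.
#' @export
generate_dataset <- function(cfg = generator_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ens <- generate_ensemble(cfg)
  files <- vapply(ens$curves, function(curve) {
    path <- file.path(dir, paste0(curve_id(curve), ".csv"))
    write_force_curve(curve, path)
    path
  }, character(1))
  manifest <- purrr::map(ens$curves, function(curve) {
    tr <- attr(curve, "truth")
    list(N = tr$N, l_app_nm = tr$l_app, L_nm = tr$L,
         velocity_nm_s = curve_velocity(curve),
         rupture = purrr::pmap(tr$chains, function(L, t_r, f_r) {
           list(t_s = t_r, f_pN = f_r, L_nm = L)
         }))
  })
  names(manifest) <- vapply(ens$curves, curve_id, character(1))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  out <- tibble(
    curve_id = names(manifest),
    file = files,
    velocity = vapply(ens$curves, curve_velocity, numeric(1))
  )
  attr(out, "manifest") <- manifest_path
  invisible(out)
}
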