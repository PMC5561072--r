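# Exponential integral E1 and its exponentially scaled form
# g(z) = exp(z) * E1(z), the kernel of the single-bond mean-force model.
# g is evaluated directly (series for z <= 1, Lentz continued fraction for
# z > 1) so that neither exp(z) nor E1(z) over/underflows on its own.

euler_gamma <- 0.577215664901532860606512

exp1_series <- function(z) {
  # E1(z) = -gamma - ln z + sum_{k>=1} (-1)^{k+1} z^k / (k k!), z <= 1
  out <- -euler_gamma - log(z)
  term <- rep(1, length(z))
  for (k in 1:40) {
    term <- term * (-z) / k
    incr <- -term / k
    out <- out + incr
    if (all(abs(incr) <= 1e-17 * abs(out))) break
  }
  out
}

exp1_cf <- function(z) {
  # Modified Lentz continued fraction for g(z) = exp(z) E1(z):
  # g(z) = 1 / (z + 1 - 1^2 / (z + 3 - 2^2 / (z + 5 - ...)))
  tiny <- 1e-300
  b <- z + 1
  c <- rep(1 / tiny, length(z))
  d <- 1 / b
  h <- d
  for (i in 1:200) {
    a <- -i * i
    b <- b + 2
    d <- 1 / (a * d + b)
    c <- b + a / c
    del <- c * d
    h <- h * del
    if (all(abs(del - 1) < 1e-15)) break
  }
  h
}

#' Exponential integral E1
#'
#' `E1(z) = integral from z to infinity of exp(-s)/s ds`, for `z > 0`.
#' Evaluated by a convergent series for `z <= 1` and a Lentz-style continued
#' fraction for `z > 1`; accurate to close to machine precision across both
#' regimes.
#'
#' @param z Positive real argument. Vectorised.
#' @return `E1(z)`.
#' @seealso [exp1_scaled()] for the overflow-safe product `exp(z) * E1(z)`.
#' @examples
#' exp1(1) # 0.2193839
#' @export
exp1 <- function(z) {
  if (any(!is.finite(z)) || any(z <= 0)) {
    abort("`z` must be positive and finite.")
  }
  out <- numeric(length(z))
  small <- z <= 1
  if (any(small)) out[small] <- exp1_series(z[small])
  if (any(!small)) out[!small] <- exp(-z[!small]) * exp1_cf(z[!small])
  out
}

#' Exponentially scaled exponential integral
#'
#' `exp1_scaled(z) = exp(z) * E1(z)`, computed without forming either factor
#' when `z` is large (where `exp(z)` overflows and `E1(z)` underflows). This
#' is the kernel of the mean-rupture-force model: the mean force over the
#' equilibrium-to-kinetic crossover is `f_eq + f_beta * exp1_scaled(1/R)`.
#' For small `z` it behaves as `-gamma - ln z`; for large `z` as `1/z`.
#'
#' @inheritParams exp1
#' @return `exp(z) * E1(z)`.
#' @export
exp1_scaled <- function(z) {
  if (any(!is.finite(z)) || any(z <= 0)) {
    abort("`z` must be positive and finite.")
  }
  out <- numeric(length(z))
  small <- z <= 1
  if (any(small)) out[small] <- exp(z[small]) * exp1_series(z[small])
  if (any(!small)) out[!small] <- exp1_cf(z[!small])
  out
}
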