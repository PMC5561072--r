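# Force-curve container and plain-text I/O.
#
# A force curve is one retraction trajectory: time (s), tip-surface
# separation (nm) and force (pN), with the retraction velocity and
# temperature carried as attributes. On disk it is a CSV with a commented
# key=value header, so a directory of such files is a dataset.

#' Construct a force curve
#'
#' @param t Time in s, strictly increasing, length >= 16.
#' @param x Tip-surface separation in nm, non-decreasing (retraction).
#' @param f Force in pN; adhesive (pulling) force is positive.
#' @param velocity Retraction velocity in nm/s.
#' @param temperature Kelvin (default 293.15, i.e. 20 degC, used when a
#'   file omits it).
#' @param curve_id Identifier string.
#' @return A tibble of class `force_curve` with columns `t`, `x`, `f` and
#'   attributes `velocity`, `temperature`, `curve_id`.
#' @export
force_curve <- function(t, x, f, velocity, temperature = 293.15,
                        curve_id = "curve") {
  n <- length(t)
  if (n < 16 || length(x) != n || length(f) != n) {
    abort("`t`, `x`, `f` must have equal length >= 16.")
  }
  if (any(diff(t) <= 0)) abort("`t` must be strictly increasing.")
  if (any(diff(x) < -1e-9)) abort("`x` must be non-decreasing on a retraction curve.")
  if (!is.finite(velocity) || velocity <= 0) abort("`velocity` must be positive (nm/s).")
  out <- tibble(t = as.numeric(t), x = as.numeric(x), f = as.numeric(f))
  attr(out, "velocity") <- velocity
  attr(out, "temperature") <- temperature
  attr(out, "curve_id") <- as.character(curve_id)
  class(out) <- c("force_curve", class(out))
  out
}

curve_velocity <- function(curve) attr(curve, "velocity")
curve_temperature <- function(curve) {
  tp <- attr(curve, "temperature")
  if (is.null(tp) || !is.finite(tp)) 293.15 else tp
}
curve_id <- function(curve) attr(curve, "curve_id") %||% "curve"

#' Write / read a force curve as commented CSV
#'
#' Format: `# key=value` header lines (`velocity_nm_s`, `temperature_K`,
#' `curve_id`) followed by CSV columns `time_s, separation_nm, force_pN`.
#'
#' @param curve A [force_curve()].
#' @param path File path.
#' @return `path` invisibly (writer); a `force_curve` (reader).
#' @export
write_force_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# velocity_nm_s=%.10g", curve_velocity(curve)),
    sprintf("# temperature_K=%.10g", curve_temperature(curve)),
    sprintf("# curve_id=%s", curve_id(curve))
  ), con)
  utils::write.csv(
    data.frame(time_s = curve$t, separation_nm = curve$x, force_pN = curve$f),
    con, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  head <- readLines(path, n = 20)
  head <- head[startsWith(head, "# ")]
  kv <- strsplit(sub("^# ", "", head), "=", fixed = TRUE)
  meta <- setNames(
    vapply(kv, function(p) paste(p[-1], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1)
  )
  raw <- utils::read.csv(path, comment.char = "#")
  force_curve(
    t = raw$time_s, x = raw$separation_nm, f = raw$force_pN,
    velocity = as.numeric(meta[["velocity_nm_s"]]),
    temperature = if ("temperature_K" %in% names(meta)) {
      as.numeric(meta[["temperature_K"]])
    } else 293.15,
    curve_id = meta[["curve_id"]] %||% basename(path)
  )
}

#' Read every force curve in a directory
#'
#' @param dir Directory containing curve CSV files (a truth `manifest.json`,
#'   if present, is ignored).
#' @return A list of `force_curve` objects.
#' @export
read_curve_dataset <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) abort(sprintf("no curve CSV files found in %s", dir))
  lapply(files, read_force_curve)
}
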