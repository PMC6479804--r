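#' Parameters of the digital-straight-segment curvature estimator
#'
#' @param km Maximum searching length in samples (>= 2).  The default, 10
#'   samples, is sized for 360 Hz recordings; [ldasg()] rescales it for
#'   other sampling rates.
#' @param delta Angle tolerance in radians (> 0) within which a run of
#'   samples still counts as digitally straight; larger values let segments
#'   grow through more noise.
#' @return An object of class `curvature_params`.
#' @export
curvature_params <- function(km = 10, delta = 0.05) {
  if (!is.numeric(km) || length(km) != 1L || km < 2 || km != round(km))
    stop("'km' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("'delta' must be a positive angle in radians", call. = FALSE)
  structure(list(km = as.integer(km), delta = as.numeric(delta)),
            class = "curvature_params")
}

#' Slope angle of the local backward chord
#'
#' Angle of the straight line from sample `i - k` to sample `i`, with time
#' measured in sample units: `atan(|x[i] - x[i-k]| / k)`.  The absolute
#' value makes rising and falling chords equivalent, so the result lies in
#' `[0, pi/2)`.
#'
#' @param x Signal (numeric or `signal_series`).
#' @param i Sample index (1-based).
#' @param k Backward distance in samples (>= 1).
#' @return Angle in radians.
#' @export
slope_angle <- function(x, i, k) {
  x <- as.numeric(x)
  if (k < 1 || i - k < 1 || i > length(x))
    stop("index out of range for slope angle", call. = FALSE)
  atan(abs(x[i] - x[i - k]) / k)
}

#' Centred slope-angle variation
#'
#' Signed difference of the chord angles one sample ahead of and one sample
#' behind `i`: `theta[i+1, k] - theta[i-1, k]`.  Zero along any straight
#' line; the straight-segment search accepts a sample while this stays
#' within the tolerance `delta`.
#'
#' @inheritParams slope_angle
#' @return Signed angle difference in radians.
#' @export
centered_slope_variation <- function(x, i, k) {
  slope_angle(x, i + 1L, k) - slope_angle(x, i - 1L, k)
}

# delta_{j,2} for every j, NA where the +/-1 neighbours or their second
# backward neighbours fall outside the record (defined for 4 <= j <= n-1).
delta2_profile <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  d <- rep(NA_real_, n)
  if (n >= 5) {
    j <- 4:(n - 1)
    d[j] <- atan(abs(x[j + 1] - x[j - 1]) / 2) -
      atan(abs(x[j - 1] - x[j - 3]) / 2)
  }
  d
}

# one-sided straight-segment growth from i; dir = -1 backward, +1 forward.
# Grows while every centred variation along the way stays within delta;
# truncates (rather than erroring) where a variation is not computable near
# the record bounds.  Minimum accepted length is 1.
dss_scan <- function(deltas, i, km, delta, dir) {
  best <- 0L
  for (s in seq_len(km)) {
    j <- i + dir * s
    if (j < 1L || j > length(deltas) || is.na(deltas[j])) break
    if (abs(deltas[j]) > delta) break
    best <- s
  }
  max(best, 1L)
}

#' Digital-straight-segment search around one sample
#'
#' Grows the longest backward and forward digitally straight segments from
#' sample `i`: the backward length `kb` is the largest `k <= km` such that
#' every centred slope variation `delta[i-s, 2]`, `s = 1..k`, lies within
#' `[-delta, delta]` (symmetrically `kf` forward; a length of 1 is always
#' accepted).  From the chord endpoints it derives the segment lengths
#' `Lb`, `Lf` (time in sample units, so `L >= k`) and slope angles
#' `theta_b`, `theta_f`.
#'
#' @param x Signal.
#' @param i Sample index (1-based), in the interior of the record.
#' @param params A [curvature_params()] object.
#' @return A list of class `dss_result` with elements `kb`, `kf`, `Lb`,
#'   `Lf`, `theta_b`, `theta_f`.
#' @export
dss_search <- function(x, i, params = curvature_params()) {
  x <- as.numeric(x)
  n <- length(x)
  if (i < 2L || i > n - 1L)
    stop("'i' must leave at least one sample on each side", call. = FALSE)
  deltas <- delta2_profile(x)
  dss_search_impl(x, i, deltas, params)
}

dss_search_impl <- function(x, i, deltas, params) {
  kb <- dss_scan(deltas, i, params$km, params$delta, -1L)
  kf <- dss_scan(deltas, i, params$km, params$delta, +1L)
  kb <- min(kb, i - 1L)            # chord endpoint must exist
  kf <- min(kf, length(x) - i)
  db <- x[i] - x[i - kb]
  df <- x[i] - x[i + kf]
  structure(list(
    kb = kb, kf = kf,
    Lb = sqrt(db^2 + kb^2), Lf = sqrt(df^2 + kf^2),
    theta_b = atan(abs(db) / kb), theta_f = atan(abs(df) / kf)
  ), class = "dss_result")
}

#' Discrete curvature at one sample
#'
#' Combines the backward/forward straight-segment lengths and slope angles
#' into the curvature estimate
#' `C = (Lb + Lf) (theta_b + theta_f) / (4 Lb Lf)`.
#' Always non-negative; zero exactly when both segment angles are zero
#' (a locally horizontal signal).
#'
#' @inheritParams dss_search
#' @return Curvature value (radians per sample-unit length).
#' @export
curvature_at <- function(x, i, params = curvature_params()) {
  d <- dss_search(x, i, params)
  (d$Lb + d$Lf) * (d$theta_b + d$theta_f) / (4 * d$Lb * d$Lf)
}

#' Noise-adaptive DSS tolerance
#'
#' Estimates the straight-segment tolerance `delta` from the signal itself:
#' 10 times the robust scale (median absolute deviation) of the centred
#' distance-2 slope variations, floored at 0.05 rad.  Rationale: a
#' neighbourhood counts as digitally straight only if all of its ~2 km
#' slope variations stay within `delta`, so `delta` must clear the
#' record-wide extreme of the noise-induced variations (about 4 robust
#' standard deviations for records of a few thousand samples) with a wide
#' margin; the curvature contrast at sharp deflections is carried by the
#' chord slope angles and is insensitive to a generous tolerance.  The
#' floor keeps `delta` positive on noise-free signals.
#'
#' @param x Signal (`signal_series` or numeric).
#' @return Tolerance in radians.
#' @export
estimate_delta <- function(x) {
  d <- delta2_profile(as.numeric(x))
  max(10 * stats::mad(d, na.rm = TRUE), 0.05)
}

#' Per-sample curvature profile
#'
#' Computes the discrete curvature at every sample that has room for both
#' the straight-segment search and the filtering window: indices
#' `max(M, 3) + 1 .. n - max(M, 3)` (1-based; three samples are the minimum
#' margin for the centred distance-2 slope variations).  Samples outside
#' this range carry `NA`.
#'
#' @param x Signal.
#' @param params A [curvature_params()] object.
#' @param exclusion Edge half-window `M` excluded at each end (>= 0).
#' @param normalize If `TRUE`, amplitudes are first rescaled to `[0, 1]`.
#'   Curvature in raw units is amplitude-dependent; normalisation makes
#'   profiles comparable across recordings with different gains.
#' @return An object of class `curvature_profile`: list with `values`
#'   (length of `x`, `NA` outside the valid range), `valid` (first and last
#'   defined index), `cmax`, `cmin`, and the parameters used.
#' @examples
#' ecg <- generate_ecg(duration = 5, seed = 1)
#' cp <- curvature_profile(ecg$signal, exclusion = 8)
#' @export
curvature_profile <- function(x, params = curvature_params(), exclusion = 0,
                              normalize = FALSE) {
  x <- as.numeric(x)
  n <- length(x)
  margin <- max(as.integer(exclusion), 3L)
  lo <- margin + 1L
  hi <- n - margin
  if (hi < lo)
    stop(sprintf("signal of length %d too short for curvature with margin %d",
                 n, margin), call. = FALSE)
  if (normalize) {
    rng <- range(x)
    if (diff(rng) > 0) x <- (x - rng[1]) / diff(rng)
  }
  deltas <- delta2_profile(x)
  values <- rep(NA_real_, n)
  for (i in lo:hi) {
    d <- dss_search_impl(x, i, deltas, params)
    values[i] <- (d$Lb + d$Lf) * (d$theta_b + d$theta_f) / (4 * d$Lb * d$Lf)
  }
  structure(list(values = values, valid = c(lo, hi),
                 cmax = max(values[lo:hi]), cmin = min(values[lo:hi]),
                 params = params, normalize = normalize),
            class = "curvature_profile")
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf("curvature_profile: %d samples, valid [%d, %d]\n",
              length(x$values), x$valid[1], x$valid[2]))
  cat(sprintf("  cmin = %.4g, cmax = %.4g (km = %d, delta = %.3g rad)\n",
              x$cmin, x$cmax, x$params$km, x$params$delta))
  invisible(x)
}
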