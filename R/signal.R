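#' Uniformly sampled signal
#'
#' A `signal_series` is a numeric amplitude vector with an attached sampling
#' rate.  The time axis is implicit and uniform: sample `i` sits at
#' `t = (i - 1) / fs` seconds, and all internal geometry (Savitzky-Golay
#' abscissae, curvature searches) works in sample units, where consecutive
#' samples are one unit apart.
#'
#' @param samples Numeric vector of amplitudes (e.g. mV).  Must be finite
#'   and of length >= 1.
#' @param fs Sampling rate in Hz (> 0).
#' @return An object of class `signal_series`: the numeric vector with an
#'   `fs` attribute.
#' @examples
#' x <- signal_series(sin(seq(0, 2 * pi, length.out = 100)), fs = 100)
#' x
#' @export
signal_series <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("'samples' must contain at least one value", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("'samples' must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  structure(samples, fs = as.numeric(fs), class = "signal_series")
}

#' Coerce to a signal_series
#'
#' Plain numeric vectors are accepted wherever a `signal_series` is, with
#' the sampling rate supplied separately (default 360 Hz, the MIT-BIH
#' arrhythmia database rate).
#'
#' @param x A `signal_series` or numeric vector.
#' @param fs Sampling rate used when `x` is a bare vector; ignored when `x`
#'   already carries one.
#' @return A `signal_series`.
#' @export
as_signal_series <- function(x, fs = 360) {
  if (inherits(x, "signal_series")) return(x)
  signal_series(x, fs)
}

#' @export
print.signal_series <- function(x, ...) {
  n <- length(x)
  cat(sprintf("signal_series: %d samples at %g Hz (%.3f s)\n",
              n, attr(x, "fs"), n / attr(x, "fs")))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' @export
plot.signal_series <- function(x, ..., xlab = "time (s)", ylab = "amplitude",
                               type = "l") {
  t <- (seq_along(x) - 1) / attr(x, "fs")
  graphics::plot(t, as.numeric(x), type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# sampling rate accessor used throughout; tolerant of bare vectors
sampling_rate <- function(x, default = 360) {
  fs <- attr(x, "fs")
  if (is.null(fs)) default else fs
}
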