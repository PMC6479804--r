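# evaluate expr under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Gaussian noise with a power-law spectrum
#'
#' Draws white Gaussian noise and shapes it in the frequency domain so the
#' power spectral density follows `S(f) proportional to 1 / f^beta`
#' (`beta = 0`: white, `beta = 1`: pink).  The DC bin is zeroed to avoid
#' the `1/0` singularity, and the output is rescaled to exactly unit mean
#' power, so callers control amplitude by multiplication.
#'
#' @param n Number of samples (>= 2).
#' @param beta Spectral exponent (>= 0).
#' @param seed Optional integer seed; the caller's RNG stream is untouched.
#' @return Numeric vector of length `n` with `mean(x^2) == 1`.
#' @examples
#' pink <- generate_colored_noise(4096, beta = 1, seed = 1)
#' @export
generate_colored_noise <- function(n, beta = 0, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("'n' must be an integer >= 2", call. = FALSE)
  if (beta < 0) stop("'beta' must be >= 0", call. = FALSE)
  w <- with_seed(seed, stats::rnorm(n))
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / n          # two-sided frequency magnitude
  amp <- ifelse(f > 0, f^(-beta / 2), 0)
  x <- Re(stats::fft(W * amp, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Band-limited surrogate for recorded muscle-artifact noise
#'
#' Electromyographic contamination of ECG concentrates its power roughly in
#' the 20-100 Hz band.  This surrogate band-passes white Gaussian noise by
#' frequency-domain masking and rescales to unit mean power.  It stands in
#' for a recorded muscle-artifact channel in tests and simulations; pass a
#' real recording to [contaminate()] via its `ma` argument when one is
#' available.
#'
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @param band Pass band in Hz, `c(low, high)`.
#' @param seed Optional seed.
#' @return Numeric vector of length `n` with unit mean power.
#' @export
ma_surrogate <- function(n, fs = 360, band = c(20, 100), seed = NULL) {
  if (n < 4) stop("'n' must be >= 4", call. = FALSE)
  if (band[1] <= 0 || band[2] <= band[1] || band[2] > fs / 2)
    stop("'band' must satisfy 0 < low < high <= fs/2", call. = FALSE)
  w <- with_seed(seed, stats::rnorm(n))
  W <- stats::fft(w)
  f <- pmin(0:(n - 1), n - (0:(n - 1))) / n * fs
  W[f < band[1] | f > band[2]] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Contaminate a clean signal at an exact SNR
#'
#' Builds a noise realisation — white Gaussian, pink (1/f), a
#' muscle-artifact channel, or an equal-or-weighted power mixture of the
#' three — and scales it so that the realised signal-to-noise ratio
#' `10 log10(P_signal / P_noise)` equals `target_snr_db` exactly for this
#' realisation (not just in expectation).
#'
#' @param x Clean signal (`signal_series` or numeric) with nonzero power.
#' @param target_snr_db Desired SNR in dB.
#' @param kind `"wgn"`, `"pink"`, `"ma"`, or `"mixture"`.
#' @param mixture_weights Relative power fractions of the wgn, pink and ma
#'   components of a mixture; must be non-negative and sum to 1.
#' @param ma Muscle-artifact noise: a numeric vector at the signal's
#'   sampling rate, or a path readable by [read_signal()].  Required when
#'   `kind` involves an ma component with positive weight; see
#'   [ma_surrogate()] for a synthetic stand-in.
#' @param seed Optional seed for the generated components.
#' @return A list of class `contamination`: `noisy` (`signal_series`),
#'   `noise` (numeric), `target_snr_db`, `kind`, `seed`.
#' @examples
#' ecg <- generate_ecg(duration = 5, seed = 2)
#' cz <- contaminate(ecg$signal, target_snr_db = 0, kind = "pink", seed = 2)
#' @export
contaminate <- function(x, target_snr_db, kind = c("wgn", "pink", "ma", "mixture"),
                        mixture_weights = c(wgn = 1, pink = 1, ma = 1) / 3,
                        ma = NULL, seed = NULL) {
  kind <- match.arg(kind)
  x <- as_signal_series(x)
  n <- length(x)
  px <- mean(as.numeric(x)^2)
  if (px == 0) stop("clean signal has zero power", call. = FALSE)

  get_ma <- function() {
    if (is.null(ma))
      stop("muscle-artifact noise requested but no 'ma' recording supplied",
           call. = FALSE)
    v <- if (is.character(ma)) as.numeric(read_signal(ma)) else as.numeric(ma)
    if (length(v) < n)
      stop("'ma' recording shorter than the signal", call. = FALSE)
    v <- v[seq_len(n)]
    v / sqrt(mean(v^2))
  }

  noise <- switch(kind,
    wgn  = generate_colored_noise(n, beta = 0, seed = seed),
    pink = generate_colored_noise(n, beta = 1, seed = seed),
    ma   = get_ma(),
    mixture = {
      w <- mixture_weights
      if (any(w < 0) || abs(sum(w) - 1) > 1e-12)
        stop("'mixture_weights' must be non-negative and sum to 1",
             call. = FALSE)
      s1 <- if (is.null(seed)) NULL else seed
      s2 <- if (is.null(seed)) NULL else seed + 1L
      comp <- cbind(
        wgn  = if (w[1] > 0) sqrt(w[1]) * generate_colored_noise(n, 0, s1) else 0,
        pink = if (w[2] > 0) sqrt(w[2]) * generate_colored_noise(n, 1, s2) else 0,
        ma   = if (w[3] > 0) sqrt(w[3]) * get_ma() else 0
      )
      rowSums(comp)
    })

  pn <- mean(noise^2)
  scale <- sqrt(px / (pn * 10^(target_snr_db / 10)))
  noise <- noise * scale
  structure(list(
    noisy = signal_series(as.numeric(x) + noise, sampling_rate(x)),
    noise = noise,
    target_snr_db = target_snr_db,
    kind = kind,
    seed = seed
  ), class = "contamination")
}

#' Synthetic quasi-periodic ECG
#'
#' Generates a clean ECG-like waveform as a train of beats, each the sum of
#' five Gaussian bumps (P, Q, R, S, T) at fixed offsets from the beat
#' anchor.  It emulates the P-QRS-T morphology, heart rate and sampling
#' rate of a real recording well enough to exercise denoising, and returns
#' the ground-truth R-peak sample indices.  It does not model baseline
#' wander, heart-rate-dependent morphology changes, or arrhythmic beats.
#'
#' @param duration Record length in seconds.
#' @param fs Sampling rate in Hz (default 360, the MIT-BIH rate).
#' @param heart_rate Beats per minute.
#' @param amplitudes Named vector of wave peak amplitudes (signal units,
#'   nominally mV) for P, Q, R, S, T.
#' @param offsets Named vector of wave-centre offsets from the R peak (s).
#' @param widths Named vector of Gaussian standard deviations (s).
#' @param rr_jitter Relative beat-to-beat interval variability (standard
#'   deviation as a fraction of the RR interval); 0 gives a strictly
#'   periodic train.
#' @param seed Optional seed (only used when `rr_jitter > 0`).
#' @return A list: `signal` (`signal_series`), `r_peaks` (1-based sample
#'   indices of the true R waves), `spec` (the parameters used).
#' @examples
#' ecg <- generate_ecg(duration = 10, heart_rate = 72)
#' length(ecg$r_peaks)  # 12 beats in 10 s at 72 bpm
#' @export
generate_ecg <- function(duration = 10, fs = 360, heart_rate = 72,
                         amplitudes = c(P = 0.15, Q = -0.1, R = 1.0,
                                        S = -0.25, T = 0.35),
                         offsets = c(P = -0.2, Q = -0.03, R = 0,
                                     S = 0.03, T = 0.3),
                         widths = c(P = 0.02, Q = 0.008, R = 0.01,
                                    S = 0.008, T = 0.05),
                         rr_jitter = 0, seed = NULL) {
  if (heart_rate <= 0) stop("'heart_rate' must be > 0", call. = FALSE)
  if (any(widths <= 0)) stop("wave widths must be > 0", call. = FALSE)
  nbeats <- floor(duration * heart_rate / 60)
  if (nbeats < 1) stop("record too short for a single beat", call. = FALSE)
  rr <- 60 / heart_rate
  anchors <- (seq_len(nbeats) - 0.5) * rr
  if (rr_jitter > 0) {
    jit <- with_seed(seed, stats::rnorm(nbeats, sd = rr_jitter * rr))
    anchors <- pmin(pmax(anchors + jit, 0), duration)
  }
  n <- round(duration * fs)
  t <- (0:(n - 1)) / fs
  x <- numeric(n)
  waves <- names(amplitudes)
  for (a in anchors)
    for (w in waves)
      x <- x + amplitudes[[w]] *
        exp(-((t - a - offsets[[w]])^2) / (2 * widths[[w]]^2))
  r_peaks <- pmin(pmax(round(anchors * fs) + 1L, 1L), n)
  list(signal = signal_series(x, fs),
       r_peaks = as.integer(r_peaks),
       spec = list(duration = duration, fs = fs, heart_rate = heart_rate,
                   amplitudes = amplitudes, offsets = offsets,
                   widths = widths, rr_jitter = rr_jitter, seed = seed))
}
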