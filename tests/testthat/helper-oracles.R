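# Independent reference implementations used to cross-check the package.
# These are deliberately written in the most literal way possible (explicit
# loops, direct formulas, no shared code with R/).

# least-squares polynomial fit of an odd window via lm(), value at centre
lm_center_fit <- function(window, N) {
  M <- (length(window) - 1) / 2
  n <- seq(-M, M)
  df <- data.frame(y = window)
  for (k in seq_len(N)) df[[paste0("p", k)]] <- n^k
  fit <- lm(y ~ ., data = df)
  unname(predict(fit, df)[M + 1])
}

# literal transcription of the straight-segment curvature search:
# nested loops, angles recomputed from scratch at every step.
brute_theta <- function(x, i, k) atan(abs(x[i] - x[i - k]) / k)

brute_delta <- function(x, j) {
  # centred distance-2 slope variation; NA when any sample is missing
  if (j - 3 < 1 || j + 1 > length(x)) return(NA_real_)
  brute_theta(x, j + 1, 2) - brute_theta(x, j - 1, 2)
}

brute_dss_side <- function(x, i, km, delta, dir) {
  best <- 0
  for (k in seq_len(km)) {
    ok <- TRUE
    for (s in seq_len(k)) {
      d <- brute_delta(x, i + dir * s)
      if (is.na(d)) { ok <- NA; break }
      if (d < -delta || d > delta) { ok <- FALSE; break }
    }
    if (is.na(ok) || !ok) break
    best <- k
  }
  max(best, 1)
}

brute_curvature <- function(x, i, km, delta) {
  kb <- min(brute_dss_side(x, i, km, delta, -1), i - 1)
  kf <- min(brute_dss_side(x, i, km, delta, +1), length(x) - i)
  Lb <- sqrt((x[i] - x[i - kb])^2 + kb^2)
  Lf <- sqrt((x[i] - x[i + kf])^2 + kf^2)
  tb <- atan(abs(x[i] - x[i - kb]) / kb)
  tf <- atan(abs(x[i] - x[i + kf]) / kf)
  (Lb + Lf) * (tb + tf) / (4 * Lb * Lf)
}

brute_profile <- function(x, km, delta, M) {
  n <- length(x)
  m <- max(M, 3)
  out <- rep(NA_real_, n)
  for (i in (m + 1):(n - m)) out[i] <- brute_curvature(x, i, km, delta)
  out
}

# standard fixed-seed noisy-ECG fixture shared by adaptive-filter tests
noisy_ecg_fixture <- function(snr_db = 5, seed = 7, duration = 10) {
  ecg <- generate_ecg(duration = duration, seed = seed)
  cz <- contaminate(ecg$signal, target_snr_db = snr_db, kind = "wgn",
                    seed = seed)
  list(clean = ecg$signal, noisy = cz$noisy, noise = cz$noise,
       r_peaks = ecg$r_peaks)
}
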