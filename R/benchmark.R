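#' Denoising benchmark over records and SNR levels
#'
#' For every combination of record, target SNR and repetition: contaminate
#' the clean record, denoise it with the curvature-adaptive filter and with
#' a fixed-order Savitzky-Golay baseline of the same window, and score both
#' against the clean record with [denoise_metrics()].  Seeds are derived
#' deterministically from `seed`, so identical calls produce identical
#' tables; input objects are never modified.
#'
#' @param records Named list of clean signals (`signal_series` or numeric
#'   vectors).
#' @param snr_levels Target SNRs in dB.
#' @param reps Noise realisations per record x SNR cell.
#' @param kind,mixture_weights,ma Passed to [contaminate()].
#' @param M,N,km,delta Adaptive-filter configuration (see [ldasg()]);
#'   `NULL` leaves the sampling-rate-scaled defaults.
#' @param baseline_order Polynomial order of the fixed SG baseline.
#' @param seed Integer master seed.
#' @return A long data frame: `record`, `snr_db`, `rep`, `method`
#'   (`"ldasg"` or `"sg"`), `snr_imp`, `mse`, `prd`.
#' @examples
#' recs <- list(synth = generate_ecg(duration = 5, seed = 3)$signal)
#' tab <- run_benchmark(recs, snr_levels = 5, reps = 1, seed = 3)
#' benchmark_summary(tab)
#' @export
run_benchmark <- function(records, snr_levels, reps = 1, kind = "wgn",
                          mixture_weights = c(wgn = 1, pink = 1, ma = 1) / 3,
                          ma = NULL, M = NULL, N = 10, km = NULL,
                          delta = NULL, baseline_order = 2, seed = 1) {
  if (reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  if (is.null(names(records)))
    names(records) <- paste0("record", seq_along(records))
  rows <- list()
  counter <- 0L
  for (rid in names(records)) {
    clean <- as_signal_series(records[[rid]])
    fs <- sampling_rate(clean)
    Mi <- if (is.null(M)) max(2L, as.integer(round(8 * fs / 360))) else M
    for (snr in snr_levels) {
      for (r in seq_len(reps)) {
        counter <- counter + 1L
        sub_seed <- (as.integer(seed) + 7919L * counter) %% .Machine$integer.max
        cz <- contaminate(clean, target_snr_db = snr, kind = kind,
                          mixture_weights = mixture_weights, ma = ma,
                          seed = sub_seed)
        fit <- ldasg(cz$noisy, M = Mi, N = N, km = km, delta = delta)
        base <- sg_filter(cz$noisy, M = Mi, N = baseline_order)
        for (method in c("ldasg", "sg")) {
          m <- denoise_metrics(clean, if (method == "ldasg") fitted(fit)
                               else base)
          rows[[length(rows) + 1L]] <- data.frame(
            record = rid, snr_db = snr, rep = r, method = method,
            snr_imp = m$snr_imp, mse = m$mse, prd = m$prd,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarise a benchmark table
#'
#' Averages the per-run metrics by method and SNR level, in the layout of
#' a published benchmark table (records averaged, one row per method x
#' SNR).
#'
#' @param tab Output of [run_benchmark()].
#' @param digits Decimal places for display rounding.
#' @return A data frame with columns `method`, `snr_db`, `snr_imp`, `mse`,
#'   `prd`.
#' @export
benchmark_summary <- function(tab, digits = 2) {
  agg <- stats::aggregate(tab[c("snr_imp", "mse", "prd")],
                          by = tab[c("method", "snr_db")], FUN = mean)
  agg$snr_imp <- round(agg$snr_imp, digits)
  agg$mse <- round(agg$mse, digits + 2)
  agg$prd <- round(agg$prd, digits)
  agg[order(agg$method, agg$snr_db), ]
}
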