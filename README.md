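# ldasg — curvature-adaptive Savitzky–Golay filtering for ECG denoising

ECG recordings mix long, nearly flat segments with very sharp QRS
deflections. A Savitzky–Golay (SG) filter — local least-squares polynomial
fitting, equivalent to convolution with fixed weights — forces one
polynomial order onto both regimes: low orders flatten R peaks, high orders
keep the noise. This package is for anyone denoising single-channel ECG
(clinical records, wearable sensors, simulation studies) who wants SG-grade
smoothing without QRS distortion.

The core idea: estimate the **discrete curvature** of every sample by
growing *digital straight segments* (DSS) on both sides — the longest runs
whose centred slope variations δ<sub>i,2</sub> = θ<sub>i+1,2</sub> −
θ<sub>i−1,2</sub> stay within a tolerance Δ — and combine their lengths and
chord angles into

C<sub>i</sub> = (L<sub>b</sub> + L<sub>f</sub>)(θ<sub>b</sub> + θ<sub>f</sub>) / (4 L<sub>b</sub> L<sub>f</sub>),

then map C(n) onto polynomial orders 1..N by uniform quantisation,

Order(n) = ⌊ N·C(n)/(C<sub>max</sub> − C<sub>min</sub>) + ½ ⌋ (clamped to [1, N]),

and filter each sample with the matching row of a precomputed SG weight
bank (one fixed window 2M+1 for the whole record; boundary samples get a
local polynomial fit). Flat stretches receive strong smoothing, QRS flanks
a high order and low distortion.

The package also ships the full evaluation protocol around the filter:
a synthetic P–QRS–T generator with ground-truth R peaks, white/pink
(S(f) ∝ 1/f^β) and muscle-artifact noise with *exact* target SNR, the
SNRimp / MSE / PRD metrics, delimited-text and WFDB (formats 16/212) input,
a benchmark harness, and a command-line front end
(`inst/cli/ldasg.R`: `denoise`, `curvature`, `simulate`, `evaluate`,
`benchmark`).

## Worked example

```r
library(ldasg)

ecg   <- generate_ecg(duration = 10, seed = 7)                  # 12 beats, 360 Hz
noisy <- contaminate(ecg$signal, target_snr_db = 5,
                     kind = "wgn", seed = 7)                    # exactly 5 dB
fit   <- ldasg(noisy$noisy)
fit
#> Low-distortion adaptive Savitzky-Golay fit
#>   3600 samples at 360 Hz; window 2M+1 = 17, orders 1..10
#>   curvature: cmin = 5.811e-06, cmax = 0.01466 (km = 10, delta = 0.54)
#>   order usage: 1:2869 2:431 3:103 4:71 5:52 6:39 7:12 8:12 9:8 10:3

denoise_metrics(ecg$signal, fitted(fit))
#> SNRimp 14.97 dB | MSE 0.001135 | PRD 17.85% (K = 3600)

denoise_metrics(ecg$signal, sg_filter(noisy$noisy, M = 8, N = 2))
#> SNRimp 12.74 dB | MSE 0.001896 | PRD 23.07% (K = 3600)
```

Reading the numbers: most samples (2869 of 3600) sit on flat baseline and
get order 1 (maximal smoothing); the QRS flanks climb to orders 8–10. The
adaptive filter reconstructs the clean signal at 14.97 dB
signal-to-distortion (PRD 17.85%), versus 12.74 dB (PRD 23.07%) for a
fixed-order SG filter with the same window — the fixed filter's extra error
is concentrated exactly at the R peaks. `plot(fit)` shows the denoised
overlay, the curvature profile and the selected orders;
`summary(fit)`, `coef(fit)` (the weight bank) and `residuals(fit)` (the
removed component) expose the rest of the fit.

The tolerance Δ is the one noise-dependent parameter; by default it is
calibrated per record as 10× the robust scale of the slope variations
(`estimate_delta()`), floored at 0.05 rad.

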