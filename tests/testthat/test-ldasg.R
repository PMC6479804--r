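make_profile <- function(values, lo, hi) {
  # hand-built curvature profile for quantisation tests
  structure(list(values = values, valid = c(lo, hi),
                 cmax = max(values[lo:hi]), cmin = min(values[lo:hi]),
                 params = curvature_params(), normalize = FALSE),
            class = "curvature_profile")
}

test_that("curvature quantises to orders by the floor rule with clamping", {
  prof <- make_profile(c(NA, NA, NA, 0, 1, 2, NA), 4, 6)
  o <- map_orders(prof, N = 10)
  # C=0 -> floor(0.5)=0 -> clamped to 1; C=1 -> floor(5.5)=5; C=2 -> floor(10.5)=10
  expect_identical(o[4:6], c(1L, 5L, 10L))
  # excluded edges inherit the nearest defined order
  expect_identical(o[1:3], rep(1L, 3))
  expect_identical(o[7], 10L)
  # degenerate profile: every order is the fallback
  flat <- make_profile(c(NA, 0.3, 0.3, 0.3, NA), 2, 4)
  expect_identical(map_orders(flat, 10, fallback_order = 4), rep(4L, 5))
  expect_error(map_orders(prof, 10, fallback_order = 11), "fallback")
})

test_that("order is non-decreasing in curvature for a fixed range", {
  vals <- seq(0, 1, length.out = 50)
  prof <- make_profile(c(NA, NA, NA, vals, NA, NA, NA), 4, 53)
  o <- map_orders(prof, N = 10)[4:53]
  expect_true(all(diff(o) >= 0))
  expect_true(all(o >= 1 & o <= 10))
})

test_that("the filter bank rows are unit-sum SG weights with paired orders", {
  bank <- build_filter_bank(N = 4, M = 2)
  expect_equal(dim(bank), c(4, 5))
  expect_equal(rowSums(bank), rep(1, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (o in 1:4) expect_equal(bank[o, ], sg_weights(2, o),
                              ignore_attr = TRUE)
  # paired-order identity inside the bank: orders 2 and 3 share weights,
  # and order 1 equals the plain moving average (pairs with order 0)
  expect_equal(bank[2, ], bank[3, ], tolerance = 1e-10)
  expect_equal(bank[1, ], rep(1 / 5, 5), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(build_filter_bank(5, 2), "2M")
})

test_that("constant and linear signals pass through the adaptive filter", {
  const <- signal_series(rep(1.7, 80), fs = 360)
  fit <- ldasg(const, M = 4, N = 6)
  expect_equal(as.numeric(fitted(fit)), rep(1.7, 80))
  # constant signal exercises the degenerate cmax == cmin path
  expect_true(all(fit$orders == fit$config$fallback_order))
  ramp <- signal_series(0.05 * (0:99) - 1, fs = 360)
  fitr <- ldasg(ramp, M = 4, N = 6)
  expect_equal(as.numeric(fitted(fitr)), as.numeric(ramp), tolerance = 1e-9)
})

test_that("degenerate order map reduces to the fixed-order SG filter", {
  const_curv <- signal_series(rep(0.4, 120), fs = 360)
  fit <- ldasg(const_curv, M = 5, N = 8, fallback_order = 3)
  ref <- sg_filter(const_curv, M = 5, N = 3)
  expect_equal(as.numeric(fitted(fit)), as.numeric(ref))
})

test_that("the fit object is deterministic, length-preserving and traced", {
  fx <- noisy_ecg_fixture(snr_db = 5, seed = 7)
  f1 <- ldasg(fx$noisy)
  f2 <- ldasg(fx$noisy)
  expect_identical(as.numeric(fitted(f1)), as.numeric(fitted(f2)))
  expect_identical(f1$orders, f2$orders)
  expect_length(fitted(f1), length(fx$noisy))
  # intermediates are consistent: orders derive from the stored profile
  expect_identical(f1$orders,
                   map_orders(f1$curvature, f1$config$N,
                              f1$config$fallback_order))
  expect_identical(dim(coef(f1)),
                   c(f1$config$N, 2L * f1$config$M + 1L))
  expect_equal(as.numeric(f1$input) - residuals(f1), as.numeric(fitted(f1)))
})

test_that("gathered convolutions equal per-sample dot products", {
  fx <- noisy_ecg_fixture(snr_db = 5, seed = 7, duration = 3)
  fit <- ldasg(fx$noisy)
  x <- as.numeric(fx$noisy)
  M <- fit$config$M
  y <- as.numeric(fitted(fit))
  for (i in seq(M + 1, length(x) - M, by = 13)) {
    h <- fit$bank[fit$orders[i], ]
    # Eq-4 convolution: y[i] = sum_m h[m] x[i - m]; symmetric window
    expect_equal(y[i], sum(h * x[(i + M):(i - M)]), tolerance = 1e-12)
  }
})

test_that("an isolated spike is assigned the top order", {
  x <- rep(0, 101); x[51] <- 1
  fit <- ldasg(signal_series(x, 360), M = 4, N = 8, delta = 0.05)
  expect_identical(fit$orders[51], 8L)
  expect_identical(which.max(fit$orders), 51L)
})

test_that("adaptive filtering beats fixed-order SG on a noisy ECG", {
  fx <- noisy_ecg_fixture(snr_db = 5, seed = 7)
  fit <- ldasg(fx$noisy)
  m <- denoise_metrics(fx$clean, fitted(fit))
  expect_gt(m$snr_imp, 0)
  base <- sg_filter(fx$noisy, M = fit$config$M, N = 2)
  r_err <- function(y) mean(abs(as.numeric(y)[fx$r_peaks] -
                                  as.numeric(fx$clean)[fx$r_peaks]))
  expect_lt(r_err(fitted(fit)), r_err(base))
})

test_that("print, summary and plot methods run cleanly", {
  fx <- noisy_ecg_fixture(snr_db = 5, seed = 7, duration = 3)
  fit <- ldasg(fx$noisy)
  expect_output(print(fit), "adaptive Savitzky-Golay")
  expect_output(print(summary(fit)), "order usage")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
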