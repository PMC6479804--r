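test_that("slope angles follow the chord geometry", {
  x <- c(0, 1, 1, 1, 0, -1)
  expect_equal(slope_angle(x, 2, 1), pi / 4)   # rise 1 over 1
  expect_equal(slope_angle(x, 4, 1), 0)        # flat
  expect_equal(slope_angle(x, 6, 1), pi / 4)   # fall 1 over 1: |.|
  expect_error(slope_angle(x, 1, 1), "range")
})

test_that("centred slope variation vanishes on straight lines and matches hand values", {
  line <- 0.7 * (1:20) + 3
  for (i in 4:17) expect_equal(centered_slope_variation(line, i, 2), 0)
  # hand computation for a flat-then-rising corner at i = 4, k = 2:
  # theta[5,2] = atan(|x5 - x3| / 2) = atan(1/2), theta[3,2] = atan(0) = 0
  x <- c(0, 0, 0, 0, 1, 2)
  expect_equal(centered_slope_variation(x, 4, 2), atan(0.5))
  expect_equal(centered_slope_variation(x, 4, 2), brute_delta(x, 4))
  # chords of equal magnitude on either side of a symmetric peak cancel
  # under the absolute value regardless of their sign: at i = 5,
  # |x6 - x4| = |x4 - x2| = 2
  peak <- c(0, 1, 2, 3, 2, 1, 0)
  expect_equal(centered_slope_variation(peak, 5, 2), 0)
})

test_that("straight-segment search grows fully on straight signals", {
  p <- curvature_params(km = 10, delta = 0.05)
  line <- 1.5 * (1:40)
  d <- dss_search(line, 20, p)
  expect_equal(d$kb, 10)
  expect_equal(d$kf, 10)
  expect_equal(d$theta_b, atan(1.5))
  expect_equal(d$theta_f, atan(1.5))
  const <- rep(2, 30)
  d0 <- dss_search(const, 15, curvature_params(km = 5, delta = 0.05))
  expect_equal(d0$Lb, 5)  # time component only
  expect_equal(d0$Lf, 5)
  expect_equal(d0$theta_b, 0)
  expect_equal(d0$theta_f, 0)
  expect_equal(curvature_at(const, 15, curvature_params(km = 5)), 0)
})

test_that("search stops where the straightness predicate first fails", {
  # piecewise-linear corner: slope 0 then slope 1
  x <- c(rep(0, 15), 1:15)
  p <- curvature_params(km = 10, delta = 0.05)
  i <- 15  # corner
  got <- dss_search(x, i, p)
  expect_equal(got$kb, brute_dss_side(x, i, 10, 0.05, -1))
  expect_equal(got$kf, brute_dss_side(x, i, 10, 0.05, +1))
  # brute force confirms the forward side stops before the corner region ends
  expect_lt(got$kf, 10)
})

test_that("production curvature equals the literal brute-force transcription", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(20:100, 1)
    x <- rnorm(n) * runif(1, 0.1, 5)
    km <- sample(2:12, 1)
    delta <- runif(1, 0.01, 0.6)
    M <- sample(1:6, 1)
    prof <- curvature_profile(x, curvature_params(km, delta), exclusion = M)
    expect_identical(prof$values, brute_profile(x, km, delta, M))
  }
})

test_that("an isolated spike has large curvature, the flat baseline zero", {
  x <- rep(0, 41); x[21] <- 1
  p <- curvature_params(km = 5, delta = 0.05)
  expect_equal(curvature_at(x, 21, p), brute_curvature(x, 21, 5, 0.05))
  expect_gt(curvature_at(x, 21, p), 0.3)
  expect_equal(curvature_at(x, 8, p), 0)
})

test_that("profiles: constants are zero, ramps uniform, offsets irrelevant", {
  p <- curvature_params()
  prof <- curvature_profile(rep(3, 50), p, exclusion = 4)
  v <- prof$values[prof$valid[1]:prof$valid[2]]
  expect_true(all(v == 0))
  expect_equal(prof$cmax, 0)
  expect_equal(prof$cmin, 0)
  # a straight ramp has identical local geometry wherever the search can
  # reach its full length km on both sides (nearer the record ends the
  # segments are truncated, shortening L)
  ramp <- 0.4 * (1:60)
  pr <- curvature_profile(ramp, p, exclusion = 4)
  inner <- (pr$valid[1] + p$km + 2):(pr$valid[2] - p$km - 2)
  vr <- pr$values[inner]
  expect_equal(max(vr) - min(vr), 0, tolerance = 1e-12)
  # translation invariance
  set.seed(3)
  x <- rnorm(80)
  p1 <- curvature_profile(x, p, exclusion = 3)
  p2 <- curvature_profile(x + 10, p, exclusion = 3)
  expect_equal(p1$values, p2$values)
  expect_error(curvature_profile(rep(1, 5), p, exclusion = 8), "short")
})

test_that("curvature is non-negative and grows with shallow-peak amplitude", {
  # below angle saturation (chord drops smaller than their time spans) the
  # apex curvature atan(d/k)/sqrt(d^2+k^2) increases with amplitude; very
  # steep peaks saturate and the estimate levels off, so the monotone
  # regime is the shallow one
  set.seed(21)
  p <- curvature_params(km = 8, delta = 0.05)
  for (rep in 1:100) {
    n <- 61
    centre <- 31
    width <- runif(1, 2.5, 6)
    amp <- runif(1, 0.1, 0.6)
    x <- amp * exp(-((1:n - centre)^2) / (2 * width^2))
    prof <- curvature_profile(x, p, exclusion = 3)
    v <- prof$values[prof$valid[1]:prof$valid[2]]
    expect_true(all(v >= 0))
    a <- runif(1, 1.05, 1.5)
    expect_gte(curvature_at(a * x, centre, p), curvature_at(x, centre, p))
  }
})

test_that("curvature maxima co-locate with the R peaks of a synthetic ECG", {
  ecg <- generate_ecg(duration = 10, seed = 7)
  prof <- curvature_profile(ecg$signal, curvature_params(), exclusion = 8)
  half_beat <- round(0.4 * 360)
  for (r in ecg$r_peaks) {
    win <- max(prof$valid[1], r - half_beat):min(prof$valid[2], r + half_beat)
    local_argmax <- win[which.max(prof$values[win])]
    expect_lte(abs(local_argmax - r), 3)
  }
})
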