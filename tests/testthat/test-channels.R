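test_that("resampling is the identity on already-uniform streams and
           interpolates irregular ones accurately", {
  t <- (0:290) / 29
  s <- sensor_stream(t, cbind(sin(t), cos(t), t), placement = "u")
  r <- resample_uniform(s, 29)
  expect_equal(r$t, t, tolerance = 1e-12)
  expect_equal(r$a, s$a, tolerance = 1e-12)

  # closed-form signal sampled on a mixed 29/58 Hz grid
  s2 <- irregular_sine_stream()
  r2 <- resample_uniform(s2, 29)
  expect_lt(max(abs(r2$a[, 1] - sin(r2$t))), 1e-3)
  expect_lt(max(abs(r2$a[, 2] - cos(r2$t))), 1e-3)
  expect_true(all(r2$t >= s2$t[1] & r2$t <= s2$t[length(s2$t)]))

  # linear interpolation midpoint
  s3 <- sensor_stream(c(0, 1), rbind(c(0, 1, 0), c(0, 0, 1)),
                      placement = "m")
  r3 <- resample_uniform(s3, 2)
  expect_equal(unname(r3$a[2, ]), c(0, 0.5, 0.5))
})

test_that("invalid sensor streams are rejected", {
  expect_error(sensor_stream(0, matrix(0, 1, 3), placement = "x"),
               "at least 2")
  expect_error(sensor_stream(c(0, 1, 1), matrix(0, 3, 3), placement = "x"),
               "strictly increasing")
  expect_error(sensor_stream(c(0, -1), matrix(0, 2, 3), placement = "x"),
               "increasing|non-negative")
})

test_that("inclination angle follows the gravity convention", {
  expect_equal(inclination_angle(c(0, -1, 0)), 0)
  expect_equal(abs(inclination_angle(c(-1, 0, 0))), 90)
  expect_equal(inclination_angle(c(-sin(pi / 6), -cos(pi / 6), 0)), 30)
  # sagittal plane uses the z component
  expect_equal(inclination_angle(c(0, -cos(pi / 4), -sin(pi / 4),
                                   NULL), plane = "zy"), 45)
  # ill-conditioned: gravity orthogonal to the measurement plane
  expect_true(is.na(inclination_angle(c(0.01, 0.01, -1), plane = "xy")))
  # vectorized over rows
  m <- rbind(c(0, -1, 0), c(-1, 0, 0))
  expect_equal(inclination_angle(m), c(0, 90))
})

test_that("pair angle cancels the proximal reference", {
  t <- (0:100) / 29
  p <- 5 * sin(t)
  d <- 20 * cos(2 * t)
  expect_equal(pair_angle(rep(0, 101), d), d)
  expect_equal(pair_angle(p, p), rep(0, 101))
  expect_equal(pair_angle(p + 10, d + 10), pair_angle(p, d))
  expect_error(pair_angle(p, d[-1]), "different grids")
})

test_that("zero-phase low-pass keeps DC and the passband, kills the stopband", {
  ch <- channel_from_fun(function(t) rep(45, length(t)))
  expect_equal(lowpass_filter(ch, 3)$angle, ch$angle, tolerance = 1e-9)

  t <- (0:(29 * 20)) / 29
  x <- sin(2 * pi * 0.5 * t) + sin(2 * pi * 12 * t)
  y <- lowpass_filter(x, 3, rate_hz = 29)
  # project onto the two design frequencies to measure realized amplitudes
  amp <- function(sig, f) {
    2 * sqrt(mean(sig * sin(2 * pi * f * t))^2 +
             mean(sig * cos(2 * pi * f * t))^2)
  }
  expect_lt(amp(y, 12) / amp(x, 12), 10^(-20 / 20))  # > 20 dB down
  expect_equal(amp(y, 0.5), 1, tolerance = 0.05)

  set.seed(1)
  noise <- rnorm(500)
  expect_lt(var(lowpass_filter(noise, 3, rate_hz = 29)), var(noise))
  expect_error(lowpass_filter(noise, 15, rate_hz = 29), "Nyquist")
})

test_that("filtering then differentiating is shift-equivariant", {
  set.seed(7)
  x <- as.numeric(stats::filter(rnorm(400), rep(1 / 10, 10), sides = 1))
  x[is.na(x)] <- 0
  k <- 17
  f <- function(z) channel_derivative(lowpass_filter(z, 3, rate_hz = 29),
                                      rate_hz = 29)
  y <- f(x)
  y_del <- f(c(rep(x[1], k), x[seq_len(length(x) - k)]))
  # compare away from the edges where the padding differs
  i <- 60:(length(x) - 60)
  expect_equal(y_del[i + k], y[i], tolerance = 1e-6)
})

test_that("derivative matches closed forms and never penalizes held postures", {
  ch <- channel_from_fun(function(t) rep(37, length(t)))
  expect_equal(channel_derivative(ch), rep(0, length(ch$t)))

  ramp <- channel_from_fun(function(t) 10 * t)
  d <- channel_derivative(ramp)
  expect_equal(d, rep(10, length(ramp$t)))

  # truncation error of central differences at 29 Hz: h^2 * f''' / 6
  sine <- channel_from_fun(function(t) sin(2 * pi * t) * 180 / pi)
  d2 <- channel_derivative(sine)
  true <- 2 * pi * cos(2 * pi * sine$t) * 180 / pi
  err <- abs(d2 - true)[2:(length(sine$t) - 1)]
  expect_lt(max(err), 3)               # oracle-computed bound (2.81 deg/s)
  expect_lt(max(err) / (360), 0.01)    # < 1% of the derivative amplitude
  expect_error(channel_derivative(c(1, 2), rate_hz = 29), "3 samples")
})

test_that("a full LE session yields the complete channel table and flags
           missing sensors per channel", {
  ses <- simulate_session("ankle_L", seed = 21)
  cs <- compute_joint_channels(ses$streams, "LE")
  expect_length(cs$channels, 10)  # 8 limb + 2 trunk
  expect_length(cs$missing, 0)

  partial <- ses$streams[setdiff(names(ses$streams), "foot_R")]
  cs2 <- compute_joint_channels(partial, "LE")
  expect_identical(cs2$missing, "ankle_R")
  expect_length(cs2$channels, 9)
})

test_that("recovered channel angles match simulator ground truth within 2 deg RMS", {
  ses <- simulate_session("ankle_L",
                          profile = impairment_profile(tracking_noise_sd = 4,
                                                       mirror_gain = 0.5,
                                                       trunk_sway_amp = 2),
                          seed = 31)
  cs <- compute_joint_channels(ses$streams, "LE")
  for (ch in colnames(ses$truth$angles)) {
    w <- analysis_window(cs$channels[[ch]])
    truth <- approx(ses$truth$t, ses$truth$angles[, ch], xout = w$t)$y
    expect_lt(sqrt(mean((w$angle - truth)^2)), 2)
  }
})
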