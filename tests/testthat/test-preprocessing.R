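test_that("still-interval calibration recovers the generator's sensor errors", {
  cfg <- sensor_config()   # accel bias (0.3, -0.2, 0.1), gyro (0.02, -0.015, 0.01)
  g <- generate_recording(calibration_schedule(), cfg, seed = 7)
  cal <- estimate_calibration(g$imu, c(0, 5))
  n_still <- 500
  tol <- 3 * cfg$noise_sd$acc / sqrt(n_still) + 5e-3  # + tremor residue
  expect_lt(max(abs(cal$accel_bias - cfg$accel_bias)), tol)
  expect_lt(max(abs(cal$gyro_bias - cfg$gyro_bias)), 3 * cfg$noise_sd$gyro / sqrt(n_still) + 5e-4)
  # hard-iron offset from the ellipsoid fit with spin coverage
  expect_true(cal$mag_fit_ok)
  expect_lt(max(abs(cal$mag_offset - cfg$mag_hard_iron)), 0.1)
})

test_that("zero-noise zero-bias input yields a null calibration estimate", {
  g <- generate_recording(activity_schedule("still", 10, "static"),
                          quiet_config(), seed = 0)
  cal <- estimate_calibration(g$imu, c(0, 5))
  expect_lt(max(abs(cal$accel_bias)), 1e-9)
  expect_lt(max(abs(cal$gyro_bias)), 1e-9)
  expect_equal(cal$accel_scale, rep(1, 3), tolerance = 1e-9)
})

test_that("magnetometer sphere fit recovers a pure offset", {
  # synthetic mag samples on a sphere of radius 50 offset by (5, 5, 5)
  set.seed(1)
  n <- 500
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  m <- 50 * u + matrix(5, n, 3)
  fit <- harpipe:::fit_mag_ellipsoid(m, 50)
  expect_true(fit$ok)
  expect_lt(max(abs(fit$offset - 5)), 0.1)
  expect_equal(fit$scale, rep(1, 3), tolerance = 1e-6)
})

test_that("calibration needs a usable still interval", {
  g <- generate_recording(activity_schedule("still", 10, "static"),
                          quiet_config(), seed = 0)
  expect_error(estimate_calibration(g$imu, c(0, 0.05)), "10 samples")
})

test_that("wavelet shrinkage denoises a noisy tone and passes smooth input", {
  set.seed(2)
  t <- seq(0, 10, by = 0.01)
  clean <- sin(2 * pi * t)
  noisy <- clean + rnorm(length(t), 0, 0.2)
  den <- denoise_gyro(noisy)
  expect_equal(length(den), length(noisy))
  expect_lt(sqrt(mean((den - clean)^2)), sqrt(mean((noisy - clean)^2)))
  # zero input -> zero output
  expect_equal(denoise_gyro(rep(0, 256)), rep(0, 256))
  # noise-free smooth input passes within 5 percent RMS (threshold ~ 0)
  expect_lt(sqrt(mean((denoise_gyro(clean) - clean)^2)) / sqrt(mean(clean^2)),
            0.05)
  expect_error(denoise_gyro(noisy, wavelet = "sym9"), "unsupported")
  expect_error(denoise_gyro(rep(1, 4), level = 3), "2\\^level")
})

test_that("denoising is idempotent-ish", {
  set.seed(3)
  x <- sin(2 * pi * seq(0, 5, by = 0.01)) + rnorm(501, 0, 0.3)
  d1 <- denoise_gyro(x)
  d2 <- denoise_gyro(d1)
  change1 <- sqrt(mean((d1 - x)^2))
  change2 <- sqrt(mean((d2 - d1)^2))
  expect_lt(change2, 0.1 * change1)
})

test_that("orientation filter: motionless identity, unit norms, skip contract", {
  g <- generate_recording(activity_schedule("still", 10, "static"),
                          quiet_config(), seed = 0)
  k <- g$imu$channel_meta$sensor_kind
  o <- fuse_orientation(g$imu$channels[, k == "acc"],
                        g$imu$channels[, k == "gyro"],
                        g$imu$channels[, k == "mag"],
                        g$imu$timestamps, beta = 0.1)
  ang <- 2 * acos(pmin(abs(o$quaternions[, 1]), 1)) * 180 / pi
  expect_lt(max(ang), 0.1)
  expect_lt(max(abs(sqrt(rowSums(o$quaternions^2)) - 1)), 1e-9)
  expect_error(fuse_orientation(g$imu$channels[, k == "acc"],
                                g$imu$channels[, k == "gyro"], NULL,
                                g$imu$timestamps, beta = -1), "beta")
  # zero-norm accelerometer samples are skipped, not fatal
  acc0 <- g$imu$channels[, k == "acc"]
  acc0[5, ] <- 0
  o2 <- fuse_orientation(acc0, g$imu$channels[, k == "gyro"], NULL,
                         g$imu$timestamps, beta = 0.1)
  expect_true(5 %in% o2$skipped)
})

test_that("orientation filter tracks a known constant-rate rotation", {
  sch <- activity_schedule(c("still", "spin z"), c(5, 10),
                          c("static", "kinematic"))
  g <- generate_recording(sch, quiet_config(), seed = 1)
  k <- g$imu$channel_meta$sensor_kind
  o <- fuse_orientation(g$imu$channels[, k == "acc"],
                        g$imu$channels[, k == "gyro"],
                        g$imu$channels[, k == "mag"],
                        g$imu$timestamps, beta = 0.1)
  err <- quat_angle_deg(o$quaternions, g$truth$orientation)
  expect_lt(mean(err[g$imu$timestamps > 5]), 2)
})

test_that("Bessel design matches the reverse-polynomial prototype", {
  # theta_1(t) = t + 1: prototype gain magnitude at the cutoff is 1/|1 + j|
  ba1 <- bessel_design(bessel_spec(1, 5), 1000)
  expect_equal(abs(filter_response(ba1$b, ba1$a, 5, 1000)), 1 / sqrt(2),
               tolerance = 1e-4)
  # known reverse Bessel polynomial tables for n = 2..4
  expect_equal(harpipe:::reverse_bessel_coefs(2), c(3, 3, 1))
  expect_equal(harpipe:::reverse_bessel_coefs(3), c(15, 15, 6, 1))
  expect_equal(harpipe:::reverse_bessel_coefs(4), c(105, 105, 45, 10, 1))
})

test_that("Bessel filter: unity DC gain, monotone response, zero-phase mode", {
  sp <- bessel_spec(4, 5)
  ba <- bessel_design(sp, 250)
  f <- seq(0, 124.9, by = 0.1)
  mr <- abs(filter_response(ba$b, ba$a, f, 250))
  expect_equal(mr[1], 1, tolerance = 1e-6)
  expect_true(all(diff(mr) <= 1e-9))
  # constant in -> constant out (H(0) = theta_n(0)/theta_n(0) = 1)
  y <- bessel_lowpass(rep(2.5, 400), sp, 250)
  expect_equal(tail(y, 200), rep(2.5, 200), tolerance = 1e-6)
  # zero-phase mode leaves a mid-band tone unshifted
  t <- seq(0, 4, by = 1 / 250)
  tone <- sin(2 * pi * 1 * t)
  yz <- bessel_lowpass(tone, sp, 250, zero_phase = TRUE)
  mid <- 200:800
  lag <- which.max(sapply(-5:5, function(L)
    sum(yz[mid + L] * tone[mid]))) - 6
  expect_equal(lag, 0)
  expect_error(bessel_design(bessel_spec(4, 200), 250), "Nyquist")
})

test_that("Bessel group delay is flatter at DC than same-order Butterworth", {
  n <- 4
  th <- harpipe:::reverse_bessel_coefs(n)
  bw <- butterworth_denominator(n)
  w <- seq(0.05, 0.5, by = 0.05)
  gd_bessel <- analog_group_delay(th[1], th, w)
  gd_butter <- analog_group_delay(1, bw, w)
  # relative slope of the group delay near DC
  rel_slope <- function(gd) max(abs(gd - gd[1])) / abs(gd[1])
  expect_lt(rel_slope(gd_bessel), rel_slope(gd_butter))
})

test_that("noise power above 5x cutoff drops by at least 20 dB (order 4)", {
  set.seed(4)
  x <- rnorm(5000)
  y <- bessel_lowpass(x, bessel_spec(4, 5), 250)
  pgram <- function(v) {
    sp <- Mod(fft(v))^2
    freqs <- (seq_along(v) - 1) * 250 / length(v)
    sum(sp[freqs > 25 & freqs < 125])
  }
  expect_lt(10 * log10(pgram(y) / pgram(x)), -20)
})

test_that("full preprocessing splits paths: calibration for IMU, Bessel for PHY", {
  g <- generate_recording(pad_schedule(), sensor_config(), seed = 5)
  pp <- preprocess_recording(g$imu, g$phy)
  # accel bias removed within noise tolerance
  still <- pp$imu$timestamps < 5
  accmag <- sqrt(rowSums(pp$imu$channels[still, 1:3]^2))
  expect_lt(abs(mean(accmag) - 9.81), 0.05)
  # physiological channels smoothed, not rescaled
  expect_lt(var(diff(pp$phy$channels[, "ecg"])), var(diff(g$phy$channels[, "ecg"])))
  expect_s3_class(pp$orientation, "orientation_series")
})
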