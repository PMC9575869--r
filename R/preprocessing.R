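#' Estimate IMU calibration from a recording
#'
#' Phase one of the three-phase calibration filter. Accelerometer bias and a
#' common scale factor are estimated from a designated still interval, using
#' the earth's gravitational field as the reference (the device is assumed
#' level and motionless there, so the mean reading should equal
#' `(0, 0, gravity)`). Gyroscope bias is the still-interval mean rate. The
#' magnetometer hard-iron offset and per-axis scale come from an axis-aligned
#' ellipsoid-to-sphere fit over the whole recording, using the earth's
#' magnetic field magnitude as the reference radius; rotation coverage (for
#' instance a calibration schedule with [generate_recording()] "spin"
#' segments) is needed for that fit to be well conditioned.
#'
#' @param rec a [raw_recording()] with acc/gyro/mag channels.
#' @param still_interval length-2 numeric, start/end of the motionless
#'   segment in seconds.
#' @param gravity reference gravity magnitude (m/s^2).
#' @param earth_field reference magnetic field magnitude (uT).
#' @return A `calibration_estimate` list with `accel_bias`, `accel_scale`,
#'   `gyro_bias`, `mag_offset`, `mag_scale` and `mag_fit_ok`.
#' @export
estimate_calibration <- function(rec, still_interval = c(0, 5),
                                 gravity = 9.81, earth_field = 50) {
  stopifnot(inherits(rec, "raw_recording"))
  # half-open interval: the sample at the right edge already belongs to the
  # next activity segment
  sel <- which(rec$timestamps >= still_interval[1] &
                 rec$timestamps < still_interval[2])
  if (length(sel) < 10) stop("still interval holds fewer than 10 samples")
  kinds <- rec$channel_meta$sensor_kind
  acc <- rec$channels[sel, kinds == "acc", drop = FALSE]
  gyr <- rec$channels[sel, kinds == "gyro", drop = FALSE]
  accel_bias <- colMeans(acc) - c(0, 0, gravity)
  corrected <- sweep(acc, 2, accel_bias)
  accel_scale <- rep(gravity / mean(sqrt(rowSums(corrected^2))), 3)
  gyro_bias <- colMeans(gyr)
  mag_all <- rec$channels[, kinds == "mag", drop = FALSE]
  mfit <- fit_mag_ellipsoid(mag_all, earth_field)
  structure(list(accel_bias = unname(accel_bias),
                 accel_scale = unname(accel_scale),
                 gyro_bias = unname(gyro_bias),
                 mag_offset = mfit$offset, mag_scale = mfit$scale,
                 mag_fit_ok = mfit$ok),
            class = "calibration_estimate")
}

# axis-aligned ellipsoid fit: a1 x^2 + a2 y^2 + a3 z^2 + a4 x + a5 y + a6 z = 1
fit_mag_ellipsoid <- function(m, earth_field) {
  fallback <- list(offset = c(0, 0, 0), scale = c(1, 1, 1), ok = FALSE)
  if (nrow(m) < 10) return(fallback)
  D <- cbind(m^2, m)
  coefs <- tryCatch(qr.solve(D, rep(1, nrow(m))), error = function(e) NULL)
  if (is.null(coefs) || any(!is.finite(coefs)) || any(coefs[1:3] <= 0))
    return(fallback)
  ctr <- -coefs[4:6] / (2 * coefs[1:3])
  G <- 1 + sum(coefs[1:3] * ctr^2)
  if (!is.finite(G) || G <= 0) return(fallback)
  radii <- sqrt(G / coefs[1:3])
  # guard against a degenerate (coverage-starved) solution
  if (any(radii <= 0) || max(radii) / min(radii) > 10) return(fallback)
  list(offset = unname(ctr), scale = unname(earth_field / radii), ok = TRUE)
}

#' Apply a calibration estimate to a recording
#'
#' Removes accelerometer/gyroscope bias and the magnetometer hard-iron
#' offset, and applies the estimated scale factors.
#'
#' @param rec a [raw_recording()].
#' @param cal a `calibration_estimate` from [estimate_calibration()].
#' @return The calibrated [raw_recording()].
#' @export
apply_calibration <- function(rec, cal) {
  stopifnot(inherits(rec, "raw_recording"), inherits(cal, "calibration_estimate"))
  kinds <- rec$channel_meta$sensor_kind
  ch <- rec$channels
  ia <- which(kinds == "acc"); ig <- which(kinds == "gyro"); im <- which(kinds == "mag")
  ch[, ia] <- sweep(sweep(ch[, ia, drop = FALSE], 2, cal$accel_bias), 2,
                    cal$accel_scale, "*")
  ch[, ig] <- sweep(ch[, ig, drop = FALSE], 2, cal$gyro_bias)
  ch[, im] <- sweep(sweep(ch[, im, drop = FALSE], 2, cal$mag_offset), 2,
                    cal$mag_scale, "*")
  rec$channels <- ch
  rec
}

## ---- discrete wavelet denoising -------------------------------------------

# orthonormal Daubechies scaling filters (PyWavelets naming: dbN has 2N taps)
wavelet_filter <- function(name) {
  switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(0.48296291314469025, 0.8365163037378079,
            0.2241438680420134, -0.12940952255092145),
    db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
            -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    stop("unsupported wavelet: ", name))
}

dwt_step <- function(x, h, g) {
  n <- length(x); L <- length(h)
  idx <- outer(2 * seq_len(n / 2) - 1, 0:(L - 1), "+")
  idx <- (idx - 1) %% n + 1
  xm <- matrix(x[idx], n / 2, L)
  list(a = drop(xm %*% h), d = drop(xm %*% g))
}

idwt_step <- function(a, d, h, g) {
  n <- 2 * length(a); L <- length(h)
  x <- numeric(n)
  for (k in seq_along(a)) {
    pos <- ((2 * (k - 1) + 0:(L - 1)) %% n) + 1
    x[pos] <- x[pos] + h * a[k] + g * d[k]
  }
  x
}

#' Wavelet shrinkage denoising for gyroscope channels
#'
#' Phase two of the calibration filter for the gyroscope: per-axis periodized
#' discrete wavelet transform, soft thresholding of the detail coefficients
#' at the universal threshold `sigma * sqrt(2 log N)` (with `sigma` the
#' median-absolute-deviation estimate from the finest detail level), and
#' inverse transform. Output length equals input length.
#'
#' @param gyro numeric vector or matrix (one column per axis).
#' @param wavelet one of `"haar"`, `"db2"`, `"db4"` (default).
#' @param level decomposition depth (default 3); series must hold at least
#'   `2^level` samples.
#' @return Denoised series, same shape as the input.
#' @export
denoise_gyro <- function(gyro, wavelet = "db4", level = 3) {
  if (is.matrix(gyro))
    return(apply(gyro, 2, denoise_gyro, wavelet = wavelet, level = level))
  n <- length(gyro)
  if (n < 2^level) stop("series shorter than 2^level samples")
  h <- wavelet_filter(wavelet)
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  # pad to a multiple of 2^level (edge replication), truncate afterwards
  block <- 2^level
  n_pad <- ceiling(n / block) * block
  x <- c(gyro, rep(gyro[n], n_pad - n))
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    st <- dwt_step(a, h, g)
    a <- st$a
    details[[j]] <- st$d
  }
  sigma <- mad(details[[1]])
  thr <- sigma * sqrt(2 * log(n_pad))
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  for (j in seq_len(level)) details[[j]] <- soft(details[[j]])
  for (j in rev(seq_len(level))) a <- idwt_step(a, details[[j]], h, g)
  a[seq_len(n)]
}

## ---- quaternion orientation filter ----------------------------------------

#' Gradient-descent quaternion orientation filter
#'
#' Phase three of the calibration filter: per sample, the quaternion
#' kinematics are integrated from the (calibrated, denoised) gyroscope, and
#' one normalized gradient-descent step of gain `beta` is applied on the
#' objective `|measured field directions - directions predicted by q|^2`
#' using the accelerometer (gravity) and, when supplied, the magnetometer
#' (earth field). This is the standard complementary filter that bounds
#' gyroscope drift. Quaternions are scalar-first, body-to-earth, renormalized
#' every step; the scalar component is non-negative at t = 0 with sign
#' continuity thereafter.
#'
#' @param acc,gyro,mag time-aligned n x 3 matrices (mag may be `NULL` for a
#'   gravity-only correction).
#' @param timestamps sample times in seconds.
#' @param beta gradient step gain (>= 0; default 0.1).
#' @param q0 initial quaternion (scalar first).
#' @return An `orientation_series` list with `timestamps`, `quaternions`
#'   (n x 4, unit norm) and `skipped` (indices where a zero-norm
#'   accelerometer sample forced the correction step to be skipped).
#' @export
fuse_orientation <- function(acc, gyro, mag = NULL, timestamps,
                             beta = 0.1, q0 = c(1, 0, 0, 0)) {
  acc <- as.matrix(acc); gyro <- as.matrix(gyro)
  if (!is.null(mag)) mag <- as.matrix(mag)
  n <- nrow(acc)
  if (nrow(gyro) != n || length(timestamps) != n)
    stop("acc, gyro and timestamps must be time-aligned")
  if (beta < 0) stop("beta must be non-negative")
  dt <- diff(timestamps)
  dt <- c(dt[1], dt)
  res <- .madgwick_core(acc, gyro, mag, dt, beta, as.numeric(q0))
  Q <- res$quaternions
  if (Q[1, 1] < 0) Q <- -Q
  structure(list(timestamps = timestamps, quaternions = Q,
                 skipped = res$skipped),
            class = "orientation_series")
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series> %d samples over %.6g s\n",
              nrow(x$quaternions), diff(range(x$timestamps))))
  invisible(x)
}

## ---- Bessel low-pass filter ------------------------------------------------

#' Bessel low-pass filter specification
#'
#' The analog prototype is `H(s) = theta_n(0) / theta_n(s / w0)` with
#' `theta_n` the degree-`n` reverse Bessel polynomial, the classic
#' maximally-flat-delay low-pass used for physiological channels because it
#' preserves waveform shape.
#'
#' @param order filter order `n >= 1` (default 4).
#' @param cutoff cutoff frequency `w0` in Hz.
#' @return A `bessel_spec` list.
#' @export
bessel_spec <- function(order = 4, cutoff) {
  if (order < 1 || order != round(order)) stop("order must be a positive integer")
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(order = as.integer(order), cutoff = cutoff, kind = "low-pass"),
            class = "bessel_spec")
}

# reverse Bessel polynomial coefficients, ascending powers:
# a_k = (2n-k)! / (2^(n-k) k! (n-k)!)
reverse_bessel_coefs <- function(n) {
  k <- 0:n
  exp(lgamma(2 * n - k + 1) - (n - k) * log(2) - lgamma(k + 1) - lgamma(n - k + 1))
}

#' Digital Bessel filter design by bilinear transform
#'
#' Discretizes the analog reverse-Bessel prototype with cutoff pre-warping so
#' the digital response at `cutoff` matches the analog prototype at `w0`.
#' DC gain is exactly 1.
#'
#' @param spec a [bessel_spec()].
#' @param sample_rate sampling rate in Hz; `cutoff` must be below Nyquist.
#' @return List with numerator `b` and denominator `a` coefficients (in
#'   `z^-1`, `a[1] = 1`).
#' @export
bessel_design <- function(spec, sample_rate) {
  stopifnot(inherits(spec, "bessel_spec"))
  if (spec$cutoff >= sample_rate / 2) stop("cutoff must be below Nyquist")
  n <- spec$order
  th <- reverse_bessel_coefs(n)          # theta_n(s), ascending
  w0 <- 2 * pi * spec$cutoff
  C <- w0 / tan(pi * spec$cutoff / sample_rate)   # pre-warped bilinear gain
  # denominator: sum_k th_k (C/w0)^k (1 - z^-1)^k (1 + z^-1)^(n-k)
  den <- numeric(n + 1)
  for (k in 0:n) {
    pk <- th[k + 1] * (C / w0)^k *
      polymul(polypow(c(1, -1), k), polypow(c(1, 1), n - k))
    den <- den + pk
  }
  num <- th[1] * polypow(c(1, 1), n)
  list(b = num / den[1], a = den / den[1])
}

polymul <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1)
  for (i in seq_along(p)) out[i + seq_along(q) - 1] <-
      out[i + seq_along(q) - 1] + p[i] * q
  out
}

polypow <- function(p, k) {
  out <- 1
  if (k > 0) for (i in seq_len(k)) out <- polymul(out, p)
  out
}

iir_filter <- function(x, b, a) {
  xp <- c(rep(0, length(b) - 1), x)
  ma <- stats::filter(xp, b, method = "convolution", sides = 1)
  ma <- as.numeric(ma)[-seq_len(length(b) - 1)]
  if (length(a) > 1)
    ma <- as.numeric(stats::filter(ma, -a[-1], method = "recursive"))
  ma
}

#' Apply a Bessel low-pass filter
#'
#' @param x numeric vector or matrix (filtered per column).
#' @param spec a [bessel_spec()].
#' @param sample_rate sampling rate in Hz.
#' @param zero_phase if `TRUE`, apply forward-backward (squared magnitude,
#'   zero phase) with reflective edge padding.
#' @return Filtered series, same shape as the input.
#' @export
bessel_lowpass <- function(x, spec, sample_rate, zero_phase = FALSE) {
  if (is.matrix(x))
    return(apply(x, 2, bessel_lowpass, spec = spec, sample_rate = sample_rate,
                 zero_phase = zero_phase))
  ba <- bessel_design(spec, sample_rate)
  if (!zero_phase) return(iir_filter(x, ba$b, ba$a))
  n <- length(x)
  npad <- min(n - 1, 3 * (spec$order + 1) * 3)
  if (npad < 1) return(iir_filter(x, ba$b, ba$a))
  left <- 2 * x[1] - x[seq(npad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - npad)]
  xp <- c(left, x, right)
  y <- iir_filter(xp, ba$b, ba$a)
  y <- rev(iir_filter(rev(y), ba$b, ba$a))
  y[npad + seq_len(n)]
}

#' Complex frequency response of a digital filter
#'
#' @param b,a transfer-function coefficients in `z^-1`.
#' @param freqs frequencies in Hz at which to evaluate.
#' @param sample_rate sampling rate in Hz.
#' @return Complex response values.
#' @export
filter_response <- function(b, a, freqs, sample_rate) {
  z <- exp(-1i * 2 * pi * freqs / sample_rate)
  vb <- vapply(z, function(zz) sum(b * zz^(seq_along(b) - 1)), complex(1))
  va <- vapply(z, function(zz) sum(a * zz^(seq_along(a) - 1)), complex(1))
  vb / va
}

#' Filter a raw recording (IMU calibration path + physiological Bessel path)
#'
#' IMU channels receive only the calibration filter (bias/scale removal and
#' wavelet gyroscope denoising); physiological channels receive only the
#' Bessel low-pass. The fitted orientation trajectory is attached for export
#' but downstream features use the filtered channel signals.
#'
#' @param imu,phy [raw_recording()] streams.
#' @param still_interval still segment for [estimate_calibration()].
#' @param beta orientation-filter gain.
#' @param bessel a [bessel_spec()] for the physiological channels.
#' @param gravity,earth_field calibration references.
#' @return List with filtered `imu`, `phy`, the `calibration` estimate and
#'   the `orientation` series.
#' @export
preprocess_recording <- function(imu, phy, still_interval = c(0, 5),
                                 beta = 0.1,
                                 bessel = bessel_spec(4, 40),
                                 gravity = 9.81, earth_field = 50) {
  cal <- estimate_calibration(imu, still_interval, gravity, earth_field)
  imu_c <- apply_calibration(imu, cal)
  kinds <- imu_c$channel_meta$sensor_kind
  ig <- which(kinds == "gyro")
  imu_c$channels[, ig] <- denoise_gyro(imu_c$channels[, ig, drop = FALSE])
  orient <- fuse_orientation(imu_c$channels[, kinds == "acc", drop = FALSE],
                             imu_c$channels[, ig, drop = FALSE],
                             imu_c$channels[, kinds == "mag", drop = FALSE],
                             imu_c$timestamps, beta = beta)
  phy_f <- phy
  phy_f$channels <- bessel_lowpass(phy$channels, bessel, phy$rate)
  list(imu = imu_c, phy = phy_f, calibration = cal, orientation = orient)
}
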