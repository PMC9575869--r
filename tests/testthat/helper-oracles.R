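# Independent oracles and shared fixtures for the test suite.

# exhaustive enumeration of monotone warping paths (feasible for m, n <= 8):
# the brute-force reference for the DTW dynamic program
brute_force_dtw <- function(p, r) {
  m <- length(p); n <- length(r)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + (p[i] - r[j])^2
    if (acc >= best) return(invisible())
    if (i == m && j == n) {
      best <<- acc
      return(invisible())
    }
    if (i < m) rec(i + 1, j, acc)
    if (j < n) rec(i, j + 1, acc)
    if (i < m && j < n) rec(i + 1, j + 1, acc)
  }
  rec(1, 1, 0)
  sqrt(best)
}

# two interleaving filament clusters (the classic semi-supervised benchmark)
make_two_moons <- function(n = 202, noise = 0.06, seed = 0) {
  set.seed(seed)
  n1 <- n %/% 2; n2 <- n - n1
  t1 <- seq(0, pi, length.out = n1)
  t2 <- seq(0, pi, length.out = n2)
  X <- rbind(cbind(cos(t1), sin(t1)),
             cbind(1 - cos(t2), 0.5 - sin(t2)))
  X <- X + matrix(rnorm(2 * n, 0, noise), ncol = 2)
  list(X = X, y = rep(c("top", "bottom"), c(n1, n2)),
       ends = c(1L, n1 + 1L))   # labeled points at the moon tips
}

# Renyi entropy (order 3) of a non-negative energy matrix
renyi_entropy <- function(E, order = 3) {
  p <- as.vector(E) / sum(E)
  p <- p[p > 0]
  log(sum(p^order)) / (1 - order)
}

# group delay of an analog prototype b(s)/a(s) at angular frequencies w,
# by numerical phase differentiation
analog_group_delay <- function(num, den, w, h = 1e-5) {
  H <- function(w1) {
    s <- 1i * w1
    vapply(s, function(ss) sum(num * ss^(seq_along(num) - 1)) /
             sum(den * ss^(seq_along(den) - 1)), complex(1))
  }
  -(Arg(H(w + h) * Conj(H(w)))) / h
}

# analog Butterworth denominator coefficients (ascending powers of s),
# poles on the unit circle, cutoff 1 rad/s
butterworth_denominator <- function(n) {
  poles <- exp(1i * pi * (2 * seq_len(n) + n - 1) / (2 * n))
  coef <- 1
  for (p in poles) coef <- c(0, coef) - c(p * coef, 0)
  Re(rev(coef))
}

# per-class Fisher ratio of a 1-D projection
fisher_ratio <- function(v, y) {
  m <- tapply(v, y, mean)
  vv <- tapply(v, y, var)
  (diff(range(m)))^2 / sum(vv)
}

# small noise-free sensor config for exact-recovery tests
quiet_config <- function(...) {
  sensor_config(noise_sd = list(acc = 0, gyro = 0, mag = 0, emg = 0, ecg = 0),
                accel_bias = c(0, 0, 0), gyro_bias = c(0, 0, 0),
                gyro_drift_rate = 0, mag_hard_iron = c(0, 0, 0), ...)
}

# schedule with rotation coverage for magnetometer calibration
calibration_schedule <- function() {
  activity_schedule(c("still", "spin z", "spin y", "spin x"),
                    c(5, 5, 5, 5),
                    c("static", "kinematic", "kinematic", "kinematic"))
}

mvn_density <- function(x, mu, S) {
  Si <- solve(S)
  dx <- sweep(x, 2, mu)
  exp(-0.5 * rowSums((dx %*% Si) * dx)) / (2 * pi * sqrt(det(S)))
}

quat_angle_deg <- function(q1, q2) {
  d <- pmin(abs(rowSums(q1 * q2)), 1)
  2 * acos(d) * 180 / pi
}
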