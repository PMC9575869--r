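test_that("DTW matches the exhaustive-path oracle on small problems", {
  set.seed(20)
  for (case in seq_len(60)) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    p <- sample(0:9, m, replace = TRUE)
    r <- sample(0:9, n, replace = TRUE)
    res <- dtw(p, r)
    expect_equal(res$cost, brute_force_dtw(p, r), tolerance = 1e-12)
    expect_gte(res$k, max(m, n))
    expect_lt(res$k, m + n - 1)
    expect_equal(res$path[1, ], c(1, 1))
    expect_equal(res$path[res$k, ], c(m, n))
    steps <- diff(res$path)
    expect_true(all(steps >= 0 & steps <= 1))
    expect_true(all(rowSums(steps) >= 1))
  }
})

test_that("DTW identity, symmetry and small worked examples", {
  p <- c(0.3, 1.2, -0.5, 2.2)
  expect_equal(dtw(p, p)$cost, 0)
  expect_equal(dtw(p, p)$k, length(p))
  expect_true(all(dtw(p, p)$path[, 1] == dtw(p, p)$path[, 2]))
  r <- c(1, 0, 2)
  expect_equal(dtw(p, r)$cost, dtw(r, p)$cost)
  # m = 3, n = 2: path length bound forces k = 3
  res <- dtw(c(1, 2, 3), c(1, 3))
  expect_equal(res$k, 3)
  expect_error(dtw(numeric(0), r), "empty")
})

test_that("Gaussian field moments: PSD covariance and known structure", {
  meta <- data.frame(name = c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y",
                              "gyro_z", "emg", "ecg"),
                     sensor_kind = c(rep("acc", 3), rep("gyro", 3),
                                     "emg", "ecg"),
                     units = "", stringsAsFactors = FALSE)
  set.seed(21)
  dat <- matrix(rnorm(200 * 8), 200, 8)
  f <- gmrf_features(dat, meta)
  expect_true(all(c("gmrf_mu.acc_mag", "gmrf_cov.acc_mag.acc_mag") %in% names(f)))
  # reconstruct the covariance and check PSD
  gs <- harpipe:::window_group_series(dat, meta)
  S <- cov(do.call(cbind, gs))
  expect_true(all(eigen(S, symmetric = TRUE)$values > -1e-9))
  # linear dependence: duplicate channel gives correlation exactly 1
  dat2 <- dat; dat2[, 8] <- 2 * dat2[, 7]
  gs2 <- harpipe:::window_group_series(dat2, meta)
  S2 <- cov(do.call(cbind, gs2))
  expect_equal(cov2cor(S2)["emg", "ecg"], 1, tolerance = 1e-12)
  expect_lt(min(eigen(S2, symmetric = TRUE)$values), 1e-8)
})

test_that("white-noise covariance off-diagonals vanish at rate 3/sqrt(n)", {
  set.seed(22)
  n <- 10000
  X <- matrix(rnorm(2 * n), n, 2)
  S <- cov(X)
  expect_lt(abs(S[1, 2]), 3 / sqrt(n))
})

test_that("MSST concentrates a pure tone and conserves energy", {
  s <- sin(2 * pi * 5 * seq(0.01, 2, by = 0.01))
  tf <- msst(s, rate = 100, M = 2)
  expect_true(all(tf$energy >= 0))
  expect_equal(sum(tf$energy), sum(tf$stft_energy), tolerance = 0.05)
  bin5 <- which.min(abs(tf$freqs - 5))
  conc <- sum(tf$energy[(bin5 - 1):(bin5 + 1), ]) / sum(tf$energy)
  expect_gte(conc, 0.9)
  # all-zero signal gives the zero matrix
  tf0 <- msst(rep(0, 200), 100)
  expect_true(all(tf0$energy == 0))
  expect_error(msst(s, 100, M = 1), "at least 2")
})

test_that("MSST iterations sharpen: Renyi entropy non-increasing in M", {
  s <- sin(2 * pi * 4 * seq(0.01, 2, by = 0.01)) +
    0.5 * sin(2 * pi * 11 * seq(0.01, 2, by = 0.01))
  ents <- vapply(2:5, function(M)
    renyi_entropy(msst(s, 100, M = M)$energy), numeric(1))
  expect_true(all(diff(ents) <= 1e-9))
})

test_that("MSST ridge of a linear chirp increases monotonically", {
  t <- seq(0.005, 4, by = 0.005)           # 200 Hz
  chirp <- sin(2 * pi * (2 * t + (8 - 2) / (2 * 4) * t^2))
  tf <- msst(chirp, 200, M = 3)
  ridge <- tf$freqs[apply(tf$energy, 2, which.max)]
  inner <- ridge[3:(length(ridge) - 2)]     # drop boundary frames
  fit <- coef(lm(inner ~ seq_along(inner)))[2]
  expect_gt(fit, 0)
  expect_true(all(diff(inner) >= -1.01 * (200 / round(0.5 * 200))))
})

test_that("HMRF segments a two-state signal and its energy trace descends", {
  set.seed(23)
  truth <- rep(c(1, 2, 1), times = c(80, 80, 40))
  sig <- rnorm(200, mean = c(0, 5)[truth], sd = 0.5)
  h <- hmrf_em(sig, n_states = 2)
  acc <- max(mean(h$states == truth), mean((3 - h$states) == truth))
  expect_gte(acc, 0.95)
  expect_true(all(diff(h$energy_trace) <= 0))
  # constant signal: one state, zero boundary energy
  hc <- hmrf_em(rep(1, 100), 2)
  expect_equal(length(unique(hc$states)), 1)
  expect_equal(tail(hc$energy_trace, 1), 0)
  expect_error(hmrf_em(sig, n_states = 1), "n_states")
  expect_error(hmrf_em(sig[1:15], n_states = 2), "too short")
})

test_that("HMRF states are permutation-invariant summaries", {
  set.seed(24)
  sig <- rnorm(200, mean = rep(c(0, 4), each = 100), sd = 0.4)
  f1 <- harpipe:::hmrf_features(hmrf_em(sig, 2))
  f2 <- harpipe:::hmrf_features(hmrf_em(-sig, 2))
  # occupancy of the low-mean state maps to the mirrored high-mean state
  expect_equal(unname(f1["hmrf_gap"]), unname(f2["hmrf_gap"]), tolerance = 0.1)
  expect_equal(unname(f1["hmrf_occ_low"]), 1 - unname(f2["hmrf_occ_low"]),
               tolerance = 0.05)
})

test_that("template bank and kinematic features behave as specified", {
  g <- generate_recording(pad_schedule(), sensor_config(), seed = 4)
  pp <- preprocess_recording(g$imu, g$phy)
  ws <- decide_patterns(make_windows(fuse_streams(pp$imu, pp$phy)))
  bank <- build_template_bank(ws, max_candidates = 10, seed = 0)
  expect_setequal(bank$channels, c("acc_mag", "gyro_mag", "emg", "ecg"))
  kin <- which(vapply(ws$windows, function(w) w$pattern == "kinematic",
                      logical(1)))
  f <- kinematic_features(ws$windows[[kin[1]]], bank, ws$channel_meta)
  f2 <- kinematic_features(ws$windows[[kin[2]]], bank, ws$channel_meta)
  expect_identical(names(f), names(f2))
  expect_true(all(f[grep("^dtw", names(f))] >= 0))
  # a window identical to its template scores a zero DTW feature
  tmpl_win <- ws$windows[[kin[1]]]
  ch <- bank$channels[1]
  act <- gsub(" ", "_", tmpl_win$label)
  bank$bank[[ch]][[tmpl_win$label]] <- harpipe:::decimate_series(
    harpipe:::zscore(harpipe:::window_group_series(
      tmpl_win$data, ws$channel_meta)[[ch]]), bank$downsample)
  f3 <- kinematic_features(tmpl_win, bank, ws$channel_meta)
  expect_equal(unname(f3[paste0("dtw.", ch, ".", act)]), 0, tolerance = 1e-12)
})

test_that("static features are deterministic and discriminative", {
  g <- generate_recording(pad_schedule(), sensor_config(), seed = 5)
  pp <- preprocess_recording(g$imu, g$phy)
  ws <- decide_patterns(make_windows(fuse_streams(pp$imu, pp$phy)))
  sta <- which(vapply(ws$windows, function(w) w$pattern == "static",
                      logical(1)))
  f1 <- static_features(ws$windows[[sta[1]]], ws$channel_meta, ws$rate)
  f1b <- static_features(ws$windows[[sta[1]]], ws$channel_meta, ws$rate)
  expect_identical(f1, f1b)
  # length formula: (bands + ridge mean/sd + log energy) per TF channel
  # plus 4 HMRF summaries per HMRF channel
  expect_length(f1, 3 * (6 + 3) + 2 * 4)
  # resting-like vs typing-like windows: inter-class exceeds intra-class
  # distance on average
  labs <- vapply(ws$windows[sta], `[[`, character(1), "label")
  F <- t(vapply(ws$windows[sta], static_features, f1,
                channel_meta = ws$channel_meta, rate = ws$rate))
  Fz <- scale(F); Fz[is.na(Fz)] <- 0
  D <- as.matrix(dist(Fz))
  same <- outer(labs, labs, "==") & upper.tri(D)
  diff_cl <- (!outer(labs, labs, "==")) & upper.tri(D)
  expect_gt(mean(D[diff_cl]), mean(D[same]))
})
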