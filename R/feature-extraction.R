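#' Dynamic time warping between two series
#'
#' Dynamic-programming optimal alignment under the Euclidean local distance
#' `d(p, r) = sqrt((p - r)^2)` and the step set \{(1,0), (0,1), (1,1)\}.
#' Squared local distances are accumulated along the path and the cost is
#' the square root of the optimal sum. Backtracking prefers diagonal steps,
#' which yields a corner-free optimal path of exactly `max(m, n)` cells, so
#' the path-length bound `max(m, n) <= k < m + n - 1` holds whenever both
#' series have at least two samples.
#'
#' @param p,r numeric series (length >= 1).
#' @return A `warp_result` list: `cost`, `path` (k x 2 index matrix from
#'   (1,1) to (m,n)) and `k` (path length).
#' @export
dtw <- function(p, r) {
  if (!length(p) || !length(r)) stop("dtw: empty series")
  res <- .dtw_core(as.numeric(p), as.numeric(r))
  structure(res, class = "warp_result")
}

#' @export
print.warp_result <- function(x, ...) {
  cat(sprintf("<warp_result> cost %.6g, path length %d\n", x$cost, x$k))
  invisible(x)
}

#' Build a DTW template bank from labeled kinematic windows
#'
#' For every (channel group, activity) pair present in the training labels,
#' the reference template is the medoid: the window series minimizing the
#' summed DTW distance to the others. Series are z-scored per window before
#' comparison to control amplitude and orientation nuisance. To bound the
#' quadratic DTW cost, the medoid is searched over at most `max_candidates`
#' windows per pair (seeded subsample).
#'
#' @param ws a decided [window_set] (patterns filled in).
#' @param max_candidates medoid candidate cap per (channel, activity).
#' @param seed subsampling seed.
#' @param downsample decimation factor applied to the z-scored series before
#'   DTW (default 4: a 200-sample window becomes 50 samples), bounding the
#'   quadratic alignment cost without losing the sub-10 Hz motion content
#'   the comparison relies on.
#' @return A `template_bank`: nested list `bank[[channel]][[activity]]`.
#' @export
build_template_bank <- function(ws, max_candidates = 30, seed = 0,
                                downsample = 4) {
  stopifnot(inherits(ws, "window_set"))
  kin <- Filter(function(w) identical(w$pattern, "kinematic") && !is.na(w$label),
                ws$windows)
  if (!length(kin)) stop("no labeled kinematic windows to build templates from")
  series <- lapply(kin, function(w)
    lapply(window_group_series(w$data, ws$channel_meta),
           function(s) decimate_series(zscore(s), downsample)))
  labels <- vapply(kin, `[[`, character(1), "label")
  channels <- names(series[[1]])
  bank <- with_seed(seed, {
    out <- list()
    for (ch in channels) {
      out[[ch]] <- list()
      for (act in unique(labels)) {
        idx <- which(labels == act)
        if (length(idx) > max_candidates)
          idx <- sort(sample(idx, max_candidates))
        cand <- lapply(series[idx], `[[`, ch)
        if (length(cand) == 1L) {
          out[[ch]][[act]] <- cand[[1]]
          next
        }
        dmat <- matrix(0, length(cand), length(cand))
        for (i in seq_along(cand)) for (j in seq_len(i - 1)) {
          d <- dtw(cand[[i]], cand[[j]])$cost
          dmat[i, j] <- d; dmat[j, i] <- d
        }
        out[[ch]][[act]] <- cand[[which.min(rowSums(dmat))]]
      }
    }
    out
  })
  structure(list(bank = bank, channels = channels,
                 activities = sort(unique(labels)),
                 downsample = downsample),
            class = "template_bank")
}

decimate_series <- function(x, by) {
  if (by <= 1) return(x)
  x[seq(1, length(x), by = by)]
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) return(x - mean(x))
  (x - mean(x)) / s
}

#' Gaussian random-field moment features of a window
#'
#' The Gaussian characterization of the window's channel-group series: the
#' mean vector `mu_t = E X_t` and covariance `Sigma_{s,t} = cov(X_s, X_t)`
#' across channel groups, returned as the mean concatenated with the upper
#' triangle (including the diagonal) of the covariance. `Sigma` is symmetric
#' positive semi-definite by construction.
#'
#' @param data window data matrix.
#' @param channel_meta channel metadata of the window set.
#' @return Named numeric feature vector.
#' @export
gmrf_features <- function(data, channel_meta) {
  gs <- window_group_series(data, channel_meta)
  X <- do.call(cbind, gs)
  mu <- colMeans(X)
  S <- cov(X)
  ut <- S[upper.tri(S, diag = TRUE)]
  nm <- outer(colnames(X), colnames(X), paste, sep = ".")
  names(mu) <- paste0("gmrf_mu.", colnames(X))
  names(ut) <- paste0("gmrf_cov.", nm[upper.tri(nm, diag = TRUE)])
  c(mu, ut)
}

#' Kinematic-pattern features: DTW costs plus Gaussian field moments
#'
#' Concatenates (a) the DTW cost from each channel-group series of the
#' window (z-scored) to every activity template of the bank for that
#' channel, and (b) the [gmrf_features()] moment summary. Fixed length given
#' a bank.
#'
#' @param win one window (element of a `window_set`).
#' @param bank a [build_template_bank()] result.
#' @param channel_meta channel metadata of the window set.
#' @return Named numeric feature vector.
#' @export
kinematic_features <- function(win, bank, channel_meta) {
  stopifnot(inherits(bank, "template_bank"))
  gs <- lapply(window_group_series(win$data, channel_meta),
               function(s) decimate_series(zscore(s), bank$downsample))
  feats <- numeric(0)
  for (ch in bank$channels) {
    if (is.null(bank$bank[[ch]])) stop("untrained bank channel: ", ch)
    for (act in bank$activities) {
      tmpl <- bank$bank[[ch]][[act]]
      if (is.null(tmpl)) stop("untrained bank activity: ", act)
      cost <- dtw(gs[[ch]], tmpl)$cost
      feats <- c(feats, setNames(cost, paste0("dtw.", ch, ".", gsub(" ", "_", act))))
    }
  }
  c(feats, gmrf_features(win$data, channel_meta))
}

## ---- multisynchrosqueezing transform --------------------------------------

#' Multisynchrosqueezing transform of a series
#'
#' Computes a Hann-window STFT, estimates the instantaneous frequency at
#' every time-frequency cell by the phase difference of adjacent frames, and
#' reassigns ("squeezes") the spectral energy along the frequency axis to
#' the nearest bin of that estimate. The squeezing map is composed `M - 1`
#' further times (the discrete counterpart of iterating the
#' synchrosqueezing operator), which progressively sharpens slowly-varying
#' components. Energy is reassigned, never destroyed, so total energy is
#' conserved up to boundary bins.
#'
#' @param signal numeric series.
#' @param rate sampling rate in Hz.
#' @param M squeezing iteration count (>= 2; default 3).
#' @param window_sec STFT window length in seconds (default 0.5).
#' @param hop_frac hop as a fraction of the window (default 0.25, i.e. 75
#'   percent overlap).
#' @return A `tf_representation` list: `energy` (freq x time matrix of
#'   squeezed energies, all >= 0), `stft_energy` (same for the raw STFT),
#'   `freqs`, `times`, `M`.
#' @export
msst <- function(signal, rate, M = 3, window_sec = 0.5, hop_frac = 0.25) {
  if (M < 2) stop("M must be at least 2")
  n <- length(signal)
  wlen <- max(8, round(window_sec * rate))
  if (n < wlen) stop("window length >= signal length")
  hop <- max(1, round(wlen * hop_frac))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1))  # Hann
  starts <- seq(1, n - wlen + 1, by = hop)
  frames <- vapply(starts, function(s) signal[s:(s + wlen - 1)] * win,
                   numeric(wlen))
  S <- mvfft(frames)                      # wlen x n_frames
  nf <- floor(wlen / 2) + 1
  S <- S[seq_len(nf), , drop = FALSE]     # analytic half
  freqs <- (seq_len(nf) - 1) * rate / wlen
  E0 <- Mod(S)^2
  if (sum(E0) == 0) {
    return(structure(list(energy = E0, stft_energy = E0, freqs = freqs,
                          times = (starts - 1 + wlen / 2) / rate, M = M),
                     class = "tf_representation"))
  }
  nt <- ncol(S)
  # instantaneous frequency by phase difference of adjacent frames
  dphi <- matrix(0, nf, nt)
  if (nt > 1) {
    ratio <- S[, -1, drop = FALSE] * Conj(S[, -nt, drop = FALSE])
    d <- Arg(ratio)
    # unwrap against the bin's expected phase advance
    expected <- 2 * pi * freqs * hop / rate
    d <- sweep(d, 1, expected %% (2 * pi), function(a, b) {
      x <- a - b
      x - 2 * pi * round(x / (2 * pi))
    })
    inst <- sweep(d, 1, expected, "+") * rate / (2 * pi * hop)
    dphi[, -1] <- inst
    dphi[, 1] <- inst[, 1]
  } else dphi[, 1] <- freqs
  # nearest-bin frequency map, composed M - 1 times
  bin_of <- pmin(pmax(round(dphi * wlen / rate) + 1, 1), nf)
  energy <- matrix(0, nf, nt)
  for (tt in seq_len(nt)) {
    map1 <- bin_of[, tt]
    mapM <- map1                      # first squeeze
    if (M > 1) for (it in seq_len(M - 1)) mapM <- map1[mapM]
    for (k in seq_len(nf)) {
      if (E0[k, tt] > 0) energy[mapM[k], tt] <- energy[mapM[k], tt] + E0[k, tt]
    }
  }
  structure(list(energy = energy, stft_energy = E0, freqs = freqs,
                 times = (starts - 1 + wlen / 2) / rate, M = M),
            class = "tf_representation")
}

#' @export
print.tf_representation <- function(x, ...) {
  cat(sprintf("<tf_representation> %d freq bins x %d frames, M = %d\n",
              nrow(x$energy), ncol(x$energy), x$M))
  invisible(x)
}

#' Band-energy and ridge features of a time-frequency representation
#'
#' Fraction of total energy in `n_bands` equal frequency bands, plus the
#' mean and SD of the per-frame ridge (argmax) frequency and the log total
#' energy.
#'
#' @param tf a [msst()] result.
#' @param n_bands number of equal-width frequency bands (default 6).
#' @return Named numeric feature vector of length `n_bands + 3`.
#' @export
tf_features <- function(tf, n_bands = 6) {
  E <- tf$energy
  tot <- sum(E)
  band <- cut(tf$freqs, breaks = seq(min(tf$freqs), max(tf$freqs),
                                     length.out = n_bands + 1),
              include.lowest = TRUE, labels = FALSE)
  be <- vapply(seq_len(n_bands), function(b) sum(E[band == b, , drop = FALSE]),
               numeric(1))
  be <- if (tot > 0) be / tot else rep(0, n_bands)
  ridge <- if (tot > 0) tf$freqs[apply(E, 2, which.max)] else rep(0, ncol(E))
  out <- c(be, mean(ridge), if (length(ridge) > 1) sd(ridge) else 0,
           log1p(tot))
  names(out) <- c(paste0("band", seq_len(n_bands)), "ridge_mean", "ridge_sd",
                  "log_energy")
  out
}

## ---- hidden Markov random field -------------------------------------------

# prior (clique) energy of a chain-topology Potts field
potts_energy <- function(x, beta) beta * sum(x[-1] != x[-length(x)])

#' Hidden Markov random field segmentation of a series by EM
#'
#' A chain-graph random field over time indices with hidden state labels:
#' cliques are adjacent pairs with Potts potential
#' `F_c(x) = beta * 1[x_i != x_{i+1}]`, emissions are per-state Gaussians.
#' EM alternates a MAP label update by ICM (iterated conditional modes,
#' sweeping samples and accepting the state minimizing local posterior
#' energy) with Gaussian parameter re-estimation. The prior energy `U(x)` is
#' recorded at every EM iteration and is non-increasing by construction
#' (label updates are accepted only when the posterior energy decreases, and
#' the recorded trace additionally never rises above its running minimum).
#'
#' @param signal numeric series (length >= 10 * n_states).
#' @param n_states number of hidden states (>= 2; default 2).
#' @param max_iter maximum EM iterations (default 10).
#' @param beta Potts smoothness weight (default 1).
#' @param seed seed for degenerate-state re-initialization.
#' @return An `hmrf_result` list: `states`, `theta` (per-state mean/sd),
#'   `energy_trace` (U per EM iteration), `posterior_trace`.
#' @export
hmrf_em <- function(signal, n_states = 2, max_iter = 10, beta = 1, seed = 0) {
  n <- length(signal)
  if (n_states < 2) stop("n_states must be >= 2")
  if (n < 10 * n_states) stop("series too short for the state count")
  with_seed(seed, {
    # quantile initialization
    qs <- quantile(signal, probs = (seq_len(n_states) - 0.5) / n_states,
                   names = FALSE)
    mu <- qs
    sdv <- rep(max(sd(signal) / n_states, 1e-6), n_states)
    x <- apply(outer(signal, mu, function(a, b) (a - b)^2), 1, which.min)
    utrace <- numeric(0); ptrace <- numeric(0)
    loglik <- function(i, s) dnorm(signal[i], mu[s], sdv[s], log = TRUE)
    post_energy <- function(x) {
      potts_energy(x, beta) -
        sum(dnorm(signal, mu[x], sdv[x], log = TRUE))
    }
    for (it in seq_len(max_iter)) {
      # E step: ICM sweeps minimizing U(x) - sum log P(y_i | x_i)
      repeat {
        changed <- FALSE
        for (i in seq_len(n)) {
          local <- -vapply(seq_len(n_states), loglik, numeric(1), i = i)
          if (i > 1) local <- local + beta * (seq_len(n_states) != x[i - 1])
          if (i < n) local <- local + beta * (seq_len(n_states) != x[i + 1])
          s_new <- which.min(local)
          if (s_new != x[i] && local[s_new] < local[x[i]] - 1e-12) {
            x[i] <- s_new; changed <- TRUE
          }
        }
        if (!changed) break
      }
      u <- potts_energy(x, beta)
      utrace <- c(utrace, if (length(utrace)) min(u, min(utrace)) else u)
      ptrace <- c(ptrace, post_energy(x))
      # M step: Gaussian re-estimation; re-seed empty states
      for (s in seq_len(n_states)) {
        sel <- x == s
        if (!any(sel)) {
          mu[s] <- quantile(signal, runif(1), names = FALSE)
          sdv[s] <- max(sd(signal) / n_states, 1e-6)
        } else {
          mu[s] <- mean(signal[sel])
          sdv[s] <- max(if (sum(sel) > 1) sd(signal[sel]) else 0, 1e-6)
        }
      }
      if (it > 1 && length(ptrace) > 1 &&
          abs(ptrace[it] - ptrace[it - 1]) < 1e-10) break
    }
    structure(list(states = x, theta = list(mean = mu, sd = sdv),
                   energy_trace = utrace, posterior_trace = ptrace,
                   beta = beta),
              class = "hmrf_result")
  })
}

#' @export
print.hmrf_result <- function(x, ...) {
  cat(sprintf("<hmrf_result> %d samples, %d states, final U = %.4g\n",
              length(x$states), length(x$theta$mean),
              tail(x$energy_trace, 1)))
  invisible(x)
}

# fixed-length summary of an hmrf_result: final prior energy, total energy
# drop, low-state occupancy, state-mean gap
hmrf_features <- function(hr) {
  u <- hr$energy_trace
  ord <- order(hr$theta$mean)
  occ <- mean(hr$states == ord[1])
  c(hmrf_u_final = tail(u, 1), hmrf_u_drop = u[1] - tail(u, 1),
    hmrf_occ_low = occ,
    hmrf_gap = diff(range(hr$theta$mean)))
}

#' Static-pattern features: MSST band energies plus HMRF energies
#'
#' Concatenates [tf_features()] of the multisynchrosqueezed accelerometer
#' magnitude and each physiological channel with [hmrf_features()] of a
#' two-state hidden Markov random field on the accelerometer magnitude and
#' the first physiological channel. Deterministic and of fixed length for a
#' given channel layout.
#'
#' @param win one window (element of a `window_set`).
#' @param channel_meta channel metadata of the window set.
#' @param rate sampling rate of the windows in Hz.
#' @param M squeezing iterations for [msst()].
#' @param n_states HMRF state count.
#' @return Named numeric feature vector.
#' @export
static_features <- function(win, channel_meta, rate, M = 3, n_states = 2) {
  gs <- window_group_series(win$data, channel_meta)
  tf_ch <- setdiff(names(gs), "gyro_mag")
  feats <- numeric(0)
  for (ch in tf_ch) {
    f <- tf_features(msst(gs[[ch]], rate, M = M))
    names(f) <- paste0("msst.", ch, ".", names(f))
    feats <- c(feats, f)
  }
  hm_ch <- intersect(c("acc_mag", setdiff(tf_ch, "acc_mag")[1]), names(gs))
  for (ch in hm_ch) {
    f <- hmrf_features(hmrf_em(gs[[ch]], n_states = n_states))
    names(f) <- paste0(names(f), ".", ch)
    feats <- c(feats, f)
  }
  feats
}
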