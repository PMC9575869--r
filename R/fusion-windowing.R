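#' Time-based fusion of IMU and physiological streams
#'
#' Combines two filtered streams onto one common clock: both are linearly
#' interpolated onto a regular grid at `target_rate` restricted to the
#' intersection of their time supports, channels are concatenated, and
#' per-sample labels are carried over from the IMU stream (nearest sample).
#'
#' @param imu,phy [raw_recording()] streams with overlapping time support.
#' @param target_rate common clock rate in Hz (default: the IMU rate, so the
#'   faster physiological stream is decimated).
#' @return A `fused_signal` list: `timestamps`, `matrix`
#'   (n x all channels), `channel_meta`, `labels`, `rate`.
#' @export
fuse_streams <- function(imu, phy, target_rate = imu$rate) {
  stopifnot(inherits(imu, "raw_recording"), inherits(phy, "raw_recording"))
  t0 <- max(min(imu$timestamps), min(phy$timestamps))
  t1 <- min(max(imu$timestamps), max(phy$timestamps))
  if (t1 <= t0) stop("streams have disjoint time supports")
  grid <- seq(ceiling(t0 * target_rate - 1e-9),
              floor(t1 * target_rate + 1e-9)) / target_rate
  interp <- function(rec) {
    apply(rec$channels, 2, function(col)
      approx(rec$timestamps, col, xout = grid)$y)
  }
  m <- cbind(interp(imu), interp(phy))
  labels <- NULL
  if (!is.null(imu$labels)) {
    nearest <- pmin(pmax(round((grid - imu$timestamps[1]) * imu$rate) + 1, 1),
                    length(imu$labels))
    labels <- imu$labels[nearest]
  }
  structure(list(timestamps = grid, matrix = m,
                 channel_meta = rbind(imu$channel_meta, phy$channel_meta),
                 labels = labels, rate = target_rate),
            class = "fused_signal")
}

#' @export
print.fused_signal <- function(x, ...) {
  cat(sprintf("<fused_signal> %d samples x %d channels @ %.6g Hz\n",
              nrow(x$matrix), ncol(x$matrix), x$rate))
  invisible(x)
}

#' Cut a fused signal into overlapping windows
#'
#' Sliding windows of `duration` seconds. The per-window sample count is
#' `round(duration * rate)` (the per-second sample count times the window
#' length); the stride is `duration * (1 - overlap)`; a trailing partial
#' window is dropped. The window label is the majority per-sample label,
#' ties resolved toward the activity that appears earlier in the window.
#'
#' @param fus a `fused_signal` from [fuse_streams()].
#' @param duration window length in seconds (default 2).
#' @param overlap overlap fraction in `[0, 1)` (default 0.5).
#' @param min_purity optional label-purity threshold; windows whose majority
#'   label covers less than this fraction are flagged `impure` (they can be
#'   excluded from training).
#' @return A `window_set` list with per-window `start`, `data`, `label`,
#'   `purity`, and a `pattern` slot (initially `"undecided"`).
#' @export
make_windows <- function(fus, duration = 2, overlap = 0.5, min_purity = 0.8) {
  stopifnot(inherits(fus, "fused_signal"))
  if (duration <= 0) stop("duration must be positive")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  m <- round(duration * fus$rate)
  stride <- max(1L, round(m * (1 - overlap)))
  n <- nrow(fus$matrix)
  if (n < m) stop("recording shorter than one window")
  starts_i <- seq(1L, n - m + 1L, by = stride)
  windows <- lapply(starts_i, function(i) {
    lab <- NA_character_; purity <- NA_real_
    if (!is.null(fus$labels)) {
      labs <- fus$labels[i:(i + m - 1L)]
      counts <- table(factor(labs, levels = unique(labs)))  # earlier-first ties
      lab <- names(counts)[which.max(counts)]
      purity <- max(counts) / m
    }
    list(start = fus$timestamps[i],
         data = fus$matrix[i:(i + m - 1L), , drop = FALSE],
         label = lab, purity = purity, pattern = "undecided")
  })
  structure(list(windows = windows, duration = duration, overlap = overlap,
                 rate = fus$rate, channel_meta = fus$channel_meta,
                 min_purity = min_purity),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %.3g s (overlap %.2g) x %d channels\n",
              length(x$windows), x$duration, x$overlap,
              nrow(x$channel_meta)))
  invisible(x)
}

#' @export
length.window_set <- function(x) length(x$windows)

# channel-group magnitude series for one window data matrix:
# ||acc||, ||gyro|| and each physiological channel as-is
window_group_series <- function(data, channel_meta) {
  kinds <- channel_meta$sensor_kind
  out <- list(
    acc_mag = sqrt(rowSums(data[, kinds == "acc", drop = FALSE]^2)),
    gyro_mag = sqrt(rowSums(data[, kinds == "gyro", drop = FALSE]^2)))
  phys <- which(kinds %in% c("emg", "ecg", "hr"))
  for (j in phys) out[[channel_meta$name[j]]] <- data[, j]
  out
}
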