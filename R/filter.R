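#' Zero-phase Butterworth low-pass filter
#'
#' Applies a second-order Butterworth low-pass filter forward and backward
#' (via [signal::filtfilt()]), giving a zero-phase, fourth-order-effective
#' response -- the standard smoothing for optical marker data, here with a
#' 6 Hz default cut-off used throughout the pipeline. Zero-phase filtering
#' avoids shifting gait-event timing.
#'
#' @param series numeric vector or T x k matrix; filtered column-wise
#' @param cutoff cut-off frequency in Hz (0 < cutoff < rate/2)
#' @param rate sampling frequency in Hz
#' @return filtered series, same shape and length as the input
#' @export
butterworth_lowpass <- function(series, cutoff, rate) {
  if (!(cutoff > 0 && cutoff < rate / 2)) {
    stop("butterworth_lowpass: cutoff must lie in (0, rate/2)")
  }
  mat <- is.matrix(series)
  x <- if (mat) series else matrix(series, ncol = 1L)
  min_len <- 12L  # 3x the effective filter order of 4
  if (nrow(x) < min_len) {
    stop("butterworth_lowpass: series too short, need at least ", min_len, " samples")
  }
  bf <- signal::butter(2L, cutoff / (rate / 2))
  # odd-reflection padding: filtfilt alone assumes zero initial conditions,
  # which injects edge transients into signals with non-zero mean
  npad <- min(6L * ceiling(rate / cutoff), nrow(x) - 1L)
  y <- apply(x, 2L, function(col) {
    n <- length(col)
    head_pad <- 2 * col[1L] - col[(npad + 1L):2L]
    tail_pad <- 2 * col[n] - col[(n - 1L):(n - npad)]
    padded <- c(head_pad, col, tail_pad)
    m <- mean(padded)
    filtered <- signal::filtfilt(bf, padded - m) + m
    filtered[(npad + 1L):(npad + n)]
  })
  if (!mat) y <- drop(y)
  else dimnames(y) <- dimnames(series)
  y
}

# Filter every marker series in a trajectory set. Gapped frames must have
# been interpolated or trimmed beforehand for the required markers.
filter_markers <- function(traj, cutoff) {
  if (is.null(cutoff)) return(traj)
  for (lb in traj$labels) {
    g <- traj$gaps[[lb]]
    if (any(g)) next  # leave gapped markers unfiltered; pipeline checks required ones
    traj$positions[[lb]] <- butterworth_lowpass(traj$positions[[lb]], cutoff, traj$rate)
  }
  traj
}
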