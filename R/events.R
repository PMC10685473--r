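#' Detect gait events from the vertical ground reaction force
#'
#' Heel strike is the first frame at which the vertical force magnitude rises
#' to or above `threshold`; toe off is the first subsequent frame at which it
#' falls below `threshold - hysteresis` (the hysteresis suppresses chatter
#' around contact). The force record must already be at the marker rate
#' (see [resample_force_to_markers()]).
#'
#' The cycle end is the next ipsilateral heel strike when a second contact
#' exists in the record; with a single force plate it usually does not, and
#' the cycle end is then extrapolated as
#' `heel_strike + (toe_off - heel_strike) / stance_fraction`
#' using the assumed stance fraction of the gait cycle (default 0.60).
#'
#' @param fp a `force_plate_record` at the marker rate
#' @param threshold contact threshold in N (default 20)
#' @param hysteresis release hysteresis in N (default 5)
#' @param stance_fraction assumed stance fraction used when no second heel
#'   strike is present (default 0.60)
#' @param cycle_frames optional known cycle duration in frames, overriding
#'   both detection and extrapolation of the cycle end
#' @return object of class `gait_events`: `heel_strike`, `toe_off` (integer
#'   frames), `cycle_end` (frame, possibly fractional when extrapolated),
#'   `stance_fraction` (achieved), `extrapolated`
#' @export
detect_gait_events <- function(fp, threshold = 20, hysteresis = 5,
                               stance_fraction = 0.60, cycle_frames = NULL) {
  fz <- abs(fp$force[, 2L])
  on <- which(fz >= threshold)
  if (!length(on)) stop("detect_gait_events: no contact found (vertical force never reaches threshold)")
  hs <- on[1L]
  after <- which(fz < (threshold - hysteresis) & seq_along(fz) > hs)
  if (!length(after)) stop("detect_gait_events: contact never released; cannot find toe off")
  to <- after[1L]
  if (!is.null(cycle_frames)) {
    ce <- hs + cycle_frames
    extrapolated <- FALSE
  } else {
    nxt <- which(fz >= threshold & seq_along(fz) > to)
    if (length(nxt)) {
      ce <- nxt[1L]
      extrapolated <- FALSE
    } else {
      ce <- hs + (to - hs) / stance_fraction
      extrapolated <- TRUE
    }
  }
  if (!(hs < to && to < ce)) stop("detect_gait_events: inconsistent event ordering")
  structure(
    list(heel_strike = hs, toe_off = to, cycle_end = ce,
         stance_fraction = (to - hs) / (ce - hs), extrapolated = extrapolated),
    class = "gait_events"
  )
}

#' @export
print.gait_events <- function(x, ...) {
  cat("<gait_events> heel strike @ frame ", x$heel_strike,
      ", toe off @ ", x$toe_off, ", cycle end @ ", round(x$cycle_end, 2),
      if (x$extrapolated) " (extrapolated)", "\n  stance fraction ",
      round(x$stance_fraction, 3), "\n", sep = "")
  invisible(x)
}

#' Normalize a time series to 101 points of the gait cycle
#'
#' Linearly interpolates the samples between heel strike and cycle end onto
#' 0, 1, ..., 100 percent of the gait cycle (101 points). The first and last
#' output samples equal the cycle's boundary values (the cycle-end boundary
#' is itself interpolated when the cycle end falls between frames).
#'
#' @param series numeric vector or T x k matrix sampled at the marker rate
#' @param events a `gait_events` object
#' @return vector of length 101, or 101 x k matrix
#' @export
normalize_gait_cycle <- function(series, events) {
  mat <- is.matrix(series)
  x <- if (mat) series else matrix(series, ncol = 1L)
  nt <- nrow(x)
  if (events$cycle_end - events$heel_strike < 1) {
    stop("normalize_gait_cycle: cycle spans fewer than 2 frames")
  }
  if (events$cycle_end > nt) {
    stop("normalize_gait_cycle: cycle end (", round(events$cycle_end, 1),
         ") beyond series length (", nt, ")")
  }
  grid <- events$heel_strike + (0:100) / 100 * (events$cycle_end - events$heel_strike)
  win <- x[ceiling(events$heel_strike):floor(events$cycle_end), , drop = FALSE]
  if (anyNA(win)) stop("normalize_gait_cycle: gaps inside the gait cycle")
  y <- apply(x, 2L, function(col) stats::approx(seq_len(nt), col, xout = grid)$y)
  if (!mat) drop(y) else y
}
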