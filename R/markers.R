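#' Marker trajectory container
#'
#' Holds labelled 3D marker position time series in the internal laboratory
#' frame (x anterior along the walking direction, y vertical up, z to the
#' subject's left), in millimetres, with per-label gap flags for frames where
#' the marker was not observed.
#'
#' @param positions named list of T x 3 numeric matrices (mm), one per marker
#' @param rate sampling frequency in Hz (> 0)
#' @param gaps optional named list of logical vectors (length T) flagging
#'   missing frames; defaults to frames containing non-finite coordinates
#' @return an object of class `marker_trajectories`
#' @export
marker_trajectories <- function(positions, rate, gaps = NULL) {
  stopifnot(is.list(positions), length(positions) >= 1L)
  labels <- names(positions)
  if (is.null(labels) || anyDuplicated(labels) || any(labels == "")) {
    stop("marker_trajectories: positions must be a named list with unique labels")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("marker_trajectories: rate must be a positive scalar (Hz)")
  }
  positions <- lapply(positions, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 3L) stop("marker_trajectories: each series must be T x 3")
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y", "z")
    p
  })
  nf <- vapply(positions, nrow, integer(1L))
  if (length(unique(nf)) != 1L) {
    stop("marker_trajectories: all marker series must have equal length")
  }
  if (is.null(gaps)) {
    gaps <- lapply(positions, function(p) !apply(is.finite(p), 1L, all))
  }
  gaps <- gaps[labels]
  for (lb in labels) {
    g <- gaps[[lb]]
    if (length(g) != nf[[1L]]) stop("marker_trajectories: gap series length mismatch for ", lb)
    if (any(!g & !apply(is.finite(positions[[lb]]), 1L, all))) {
      stop("marker_trajectories: non-finite coordinates at unflagged frames for ", lb)
    }
  }
  structure(
    list(labels = labels, positions = positions, rate = as.numeric(rate), gaps = gaps),
    class = "marker_trajectories"
  )
}

#' @export
print.marker_trajectories <- function(x, ...) {
  cat("<marker_trajectories> ", length(x$labels), " markers x ",
      n_frames(x), " frames @ ", x$rate, " Hz\n", sep = "")
  cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  ngap <- sum(vapply(x$gaps, sum, numeric(1L)))
  if (ngap > 0) cat("  gapped samples:", ngap, "\n")
  invisible(x)
}

#' Number of frames in a marker trajectory set
#' @param traj a `marker_trajectories` object
#' @export
n_frames <- function(traj) nrow(traj$positions[[1L]])

#' Frame times (s) of a marker trajectory set
#' @param traj a `marker_trajectories` object
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1L) / traj$rate

marker <- function(traj, label) {
  p <- traj$positions[[label]]
  if (is.null(p)) stop("marker '", label, "' not present")
  p
}

#' Interpolate short marker gaps
#'
#' Linearly interpolates gaps of at most `max_gap` consecutive frames per
#' marker. Longer gaps are left flagged; [joint_angle_pipeline()] treats a
#' long gap in a required marker as an error. Leading/trailing gaps are not
#' filled.
#'
#' @param traj a `marker_trajectories` object
#' @param max_gap longest run of missing frames (in frames) that is filled
#' @return a `marker_trajectories` object with short gaps filled
#' @export
interpolate_gaps <- function(traj, max_gap = 5L) {
  for (lb in traj$labels) {
    g <- traj$gaps[[lb]]
    if (!any(g)) next
    runs <- rle(g)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    p <- traj$positions[[lb]]
    idx <- which(!g)
    for (k in seq_along(runs$lengths)) {
      if (!runs$values[k]) next
      if (runs$lengths[k] > max_gap) next
      if (starts[k] == 1L || ends[k] == n_frames(traj)) next
      fill <- starts[k]:ends[k]
      for (j in 1:3) {
        p[fill, j] <- stats::approx(idx, p[idx, j], xout = fill)$y
      }
      traj$gaps[[lb]][fill] <- FALSE
    }
    traj$positions[[lb]] <- p
  }
  traj
}

# Subset markers, keeping class invariants.
select_markers <- function(traj, labels) {
  missing <- setdiff(labels, traj$labels)
  if (length(missing)) {
    stop("missing required marker(s): ", paste(missing, collapse = ", "))
  }
  marker_trajectories(traj$positions[labels], traj$rate, traj$gaps[labels])
}
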