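#' Construct a segment-fixed coordinate frame from three markers
#'
#' The segment z-axis points from the origin marker to the long-axis marker;
#' the x-axis is the right-handed normal of the plane spanned by the origin,
#' long-axis and plane markers (`x = unit((plane - origin) x z)`); the y-axis
#' completes the right-handed triad (`y = z x x`). Fixed offsets are then
#' applied as intrinsic rotations about the segment's own axes in the order
#' x, y, z.
#'
#' @param origin,long_axis,plane 3D marker positions (mm)
#' @param rx,ry,rz offset rotations in degrees
#' @return list with elements `R` (3x3 orientation, lab <- segment columns),
#'   `origin` and `length` (origin to long-axis marker distance, mm)
#' @export
build_segment_frame <- function(origin, long_axis, plane, rx = 0, ry = 0, rz = 0) {
  zv <- long_axis - origin
  zn <- sqrt(sum(zv^2))
  if (zn == 0) stop("build_segment_frame: origin and long-axis markers coincide")
  z <- zv / zn
  pv <- plane - origin
  xv <- cross3(pv, z)
  xn <- sqrt(sum(xv^2))
  if (xn < 1e-9 * max(zn, sqrt(sum(pv^2)))) {
    stop("build_segment_frame: degenerate frame, the three markers are collinear")
  }
  x <- xv / xn
  y <- cross3(z, x)
  R <- cbind(x, y, z, deparse.level = 0)
  if (rx != 0) R <- R %*% rot_x(rx)
  if (ry != 0) R <- R %*% rot_y(ry)
  if (rz != 0) R <- R %*% rot_z(rz)
  list(R = R, origin = origin, length = zn)
}

#' Per-frame segment poses from marker trajectories
#'
#' Applies [build_segment_frame()] frame by frame for each segment
#' definition. Virtual markers must already be present (see
#' [compute_virtual_markers()]). Frames where any defining marker is gapped
#' yield a gapped pose.
#'
#' @param traj a `marker_trajectories` object including virtual markers
#' @param defs segment definitions from [segment_definitions()]
#' @return named list of `segment_pose` objects, each with `name`, `R`
#'   (3x3xT), `origin` (T x 3, mm), `length` (T, mm) and `gap` (logical T)
#' @export
pose_time_series <- function(traj, defs) {
  nt <- n_frames(traj)
  out <- vector("list", length(defs))
  names(out) <- names(defs)
  for (nm in names(defs)) {
    d <- defs[[nm]]
    need <- c(d$origin, d$long_axis, d$plane)
    missing <- setdiff(need, traj$labels)
    if (length(missing)) {
      stop("pose_time_series: segment '", nm, "' needs missing marker(s): ",
           paste(missing, collapse = ", "))
    }
    O <- traj$positions[[d$origin]]
    L <- traj$positions[[d$long_axis]]
    P <- traj$positions[[d$plane]]
    gap <- traj$gaps[[d$origin]] | traj$gaps[[d$long_axis]] | traj$gaps[[d$plane]]
    R <- array(NA_real_, c(3L, 3L, nt))
    len <- rep(NA_real_, nt)
    for (t in seq_len(nt)) {
      if (gap[t]) next
      fr <- build_segment_frame(O[t, ], L[t, ], P[t, ], d$rx, d$ry, d$rz)
      R[, , t] <- fr$R
      len[t] <- fr$length
    }
    out[[nm]] <- structure(
      list(name = nm, R = R, origin = O, length = len, gap = gap, rate = traj$rate),
      class = "segment_pose"
    )
  }
  out
}

#' @export
print.segment_pose <- function(x, ...) {
  cat("<segment_pose> ", x$name, ": ", dim(x$R)[3L], " frames, mean length ",
      round(mean(x$length, na.rm = TRUE), 1), " mm\n", sep = "")
  invisible(x)
}
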