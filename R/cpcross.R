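#' Estimate the stance-phase progression axis
#'
#' The walking direction is estimated from the displacement of the bottom
#' calcaneus (BC) marker between heel strike and cycle end, projected onto
#' the horizontal plane and normalized. Used to decide when the centre of
#' pressure has crossed "anterior" to a joint centre.
#'
#' @param traj `marker_trajectories` including BC
#' @param events a `gait_events`
#' @return unit 3-vector in the lab frame (zero vertical component)
#' @export
progression_axis <- function(traj, events) {
  bc <- marker(traj, "BC")
  d <- bc[min(round(events$cycle_end), nrow(bc)), ] - bc[events$heel_strike, ]
  d[2L] <- 0
  if (sqrt(sum(d^2)) < 1e-6) {
    stop("progression_axis: no horizontal BC displacement over the cycle")
  }
  unit3(d)
}

#' Apply CPcross masking to joint kinetics
#'
#' With a single force plate the full ground reaction is attributed to every
#' joint's distal free body, which overstates the load on the distal joints
#' early in stance while the centre of pressure is still behind them. The
#' CPcross convention reports a joint's kinetics only from the moment the
#' CoP has crossed anterior to that joint's centre. As the CoP progresses
#' from heel to toe it crosses the joints in anatomical order, so the
#' crossing indices are non-decreasing from ankle to 1st MTP.
#'
#' Masking only sets visibility flags; the moment and power values
#' themselves are left untouched.
#'
#' @param kinetics a `joint_kinetics_set` normalized to the gait cycle
#'   (i.e. produced with `events`)
#' @param fp the `force_plate_record` at marker rate used for the kinetics
#' @param poses the segment pose list
#' @param events the `gait_events`
#' @param axis progression unit vector, e.g. from [progression_axis()]
#' @return the `joint_kinetics_set` with `masked` flags and
#'   `crossing_index` (percent of gait cycle, 0-100) per joint
#' @export
cpcross_mask <- function(kinetics, fp, poses, events, axis) {
  stopifnot(inherits(kinetics, "joint_kinetics_set"))
  if (is.null(kinetics$events)) {
    stop("cpcross_mask: kinetics must be normalized to the gait cycle")
  }
  cop101 <- normalize_cop(fp, events)
  joints <- foot_joints()
  for (i in seq_len(nrow(joints))) {
    jn <- joints$joint[i]
    c101 <- normalize_gait_cycle(joint_centre_series(poses, jn), events)
    ahead <- rowSums(sweep(cop101 - c101, 2L, axis, `*`)) > 0
    ahead[!stats::complete.cases(cop101)] <- FALSE
    idx <- which(ahead)
    if (!length(idx)) {
      warning("cpcross_mask: CoP never crosses anterior to ", jn,
              "; joint fully masked")
      kinetics$joints[[jn]]$crossing_index <- NA_real_
      kinetics$joints[[jn]]$masked <- rep(TRUE, 101L)
    } else {
      cross <- idx[1L] - 1L   # percent of cycle, grid is 0..100
      kinetics$joints[[jn]]$crossing_index <- cross
      kinetics$joints[[jn]]$masked <- (0:100) < cross
    }
  }
  kinetics
}

# CoP series interpolated onto the 101-point cycle grid; NA outside contact.
normalize_cop <- function(fp, events) {
  nt <- nrow(fp$cop)
  grid <- events$heel_strike + (0:100) / 100 * (events$cycle_end - events$heel_strike)
  out <- matrix(NA_real_, 101L, 3L)
  valid <- which(fp$cop_valid)
  if (length(valid) >= 2L) {
    inside <- grid >= valid[1L] & grid <= valid[length(valid)]
    for (j in 1:3) {
      out[inside, j] <- stats::approx(valid, fp$cop[valid, j],
                                      xout = grid[inside])$y
    }
  }
  out
}
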