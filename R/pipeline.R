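#' Clinical sign convention for Cardan angles
#'
#' Internal segment frames are right-handed with z anterior and y up; the
#' x-axis then necessarily points to the subject's right on both sides
#' (lateral for the right foot, medial for the left). A positive raw
#' rotation about x tips the segment long axis down (plantarflexion) on
#' either side, so the sagittal sign is side-invariant; positive raw
#' rotations about z and y tip the sole and swing the toes toward the
#' subject's right, which is eversion/external rotation on the right side
#' but inversion/internal rotation on the left. The clinical convention
#' (dorsiflexion+, inversion+, internal rotation+ / abduction+ for the
#' hallux) therefore needs the component-wise signs (-1, -1, -1) on the
#' right and (-1, +1, +1) on the left.
#'
#' @param side `"right"` or `"left"`
#' @return length-3 sign vector applied to raw (alpha_x, beta_z, gamma_y)
#' @keywords internal
clinical_sign <- function(side) {
  if (side == "right") c(-1, -1, -1) else c(-1, 1, 1)
}

joint_angle_labels <- function(joint) {
  frontal <- "inversion(+)/eversion(-)"
  transverse <- if (joint == "mtp1") "abduction(+)/adduction(-)"
                else "internal(+)/external(-) rotation"
  c(alpha_x = "dorsiflexion(+)/plantarflexion(-)",
    beta_z = frontal, gamma_y = transverse)
}

#' Intersegmental Cardan angles for one joint
#'
#' Extracts x-z-y Cardan angles from a relative-rotation series and applies
#' the clinical sign convention.
#'
#' @param R_rel 3x3xT array from [relative_rotation()]
#' @param side `"right"` or `"left"`
#' @return T x 3 matrix with columns `alpha_x` (sagittal), `beta_z`
#'   (frontal), `gamma_y` (transverse), degrees
#' @export
joint_cardan_angles <- function(R_rel, side = "right") {
  nt <- dim(R_rel)[3L]
  out <- matrix(NA_real_, nt, 3L,
                dimnames = list(NULL, c("alpha_x", "beta_z", "gamma_y")))
  s <- clinical_sign(side)
  for (t in seq_len(nt)) {
    if (!anyNA(R_rel[, , t])) out[t, ] <- s * cardan_xzy(R_rel[, , t])
  }
  out
}

#' Full kinematic pipeline: markers to normalized joint angles and MLA
#'
#' Runs the complete kinematic chain: short-gap interpolation, zero-phase
#' low-pass filtering of the markers, virtual-marker construction,
#' segment-frame pose estimation, intersegmental x-z-y Cardan angles for the
#' four joints (ankle = hindfoot vs shank, Chopart = midfoot vs hindfoot,
#' Lisfranc = forefoot vs midfoot, 1st MTP = hallux vs forefoot), the MLA
#' height/length ratio, gait-event detection from the force record, and
#' normalization of every curve to 101 points of the gait cycle.
#'
#' @param traj a `marker_trajectories` object with the canonical marker set
#' @param fp a `force_plate_record` (any rate; resampled internally)
#' @param config a [trial_config()]
#' @param events optional pre-computed `gait_events` (otherwise detected)
#' @return list of class `foot_kinematics`:
#'   \item{angles}{named list (ankle, chopart, lisfranc, mtp1) of 101 x 3
#'     angle matrices (degrees, clinical signs)}
#'   \item{mla}{`mla_series` of 101 samples}
#'   \item{events}{`gait_events`}
#'   \item{poses}{segment pose series (unnormalized, full trial)}
#'   \item{fp}{force record resampled to the marker rate}
#'   \item{traj}{the filtered trajectories with virtual markers}
#' @export
joint_angle_pipeline <- function(traj, fp, config = trial_config(), events = NULL) {
  registry <- marker_set_registry(config$side)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("joint_angle_pipeline [", name, "]: ", conditionMessage(e), call. = FALSE)
    })
  }
  stage("markers", check_required_markers(traj$labels, registry))
  if (!is.null(config$filter_cutoff) && config$filter_cutoff >= traj$rate / 2) {
    stop("joint_angle_pipeline [filter]: cutoff must be below the marker Nyquist frequency")
  }
  traj <- stage("gaps", interpolate_gaps(traj))
  req <- c(registry$physical, registry$shank)
  long_gaps <- req[vapply(req, function(lb) any(traj$gaps[[lb]]), logical(1L))]
  if (length(long_gaps)) {
    stop("joint_angle_pipeline [gaps]: unfillable gaps in required marker(s): ",
         paste(long_gaps, collapse = ", "))
  }
  traj <- stage("filter", filter_markers(traj, config$filter_cutoff))
  traj <- stage("virtual", compute_virtual_markers(traj, registry))
  defs <- segment_definitions(config$side)
  poses <- stage("frames", pose_time_series(traj, defs))

  joints <- foot_joints()
  raw_angles <- lapply(seq_len(nrow(joints)), function(i) {
    stage(joints$joint[i], {
      R_rel <- relative_rotation(poses[[joints$child[i]]], poses[[joints$parent[i]]])
      joint_cardan_angles(R_rel, config$side)
    })
  })
  names(raw_angles) <- joints$joint

  mla_full <- stage("mla", mla_ratio(marker(traj, "BC"), marker(traj, "MTH1"),
                                     marker(traj, "NV")))

  fp60 <- stage("resample", {
    if (!is.null(config$grf_cutoff)) {
      fp$force <- butterworth_lowpass(fp$force, config$grf_cutoff, fp$rate)
    }
    resample_force_to_markers(fp, traj$rate)
  })
  if (is.null(events)) {
    events <- stage("events", detect_gait_events(
      fp60, threshold = config$contact_threshold,
      stance_fraction = config$stance_fraction))
  }

  angles <- lapply(raw_angles, function(a) stage("normalize", {
    out <- normalize_gait_cycle(a, events)
    colnames(out) <- colnames(a)
    out
  }))
  mla <- stage("normalize", {
    m <- normalize_gait_cycle(as.matrix(mla_full), events)
    structure(as.data.frame(m), names = c("length", "height", "ratio"),
              class = c("mla_series", "data.frame"))
  })

  structure(
    list(angles = angles, mla = mla, events = events, poses = poses,
         fp = fp60, traj = traj, side = config$side),
    class = "foot_kinematics"
  )
}

#' @export
print.foot_kinematics <- function(x, ...) {
  cat("<foot_kinematics> side:", x$side, "\n")
  for (j in names(x$angles)) {
    rng <- apply(x$angles[[j]], 2L, function(v) diff(range(v)))
    cat(sprintf("  %-9s ROM (deg): sagittal %5.1f frontal %5.1f transverse %5.1f\n",
                j, rng[1L], rng[2L], rng[3L]))
  }
  cat(sprintf("  MLA ratio: %.3f - %.3f\n", min(x$mla$ratio), max(x$mla$ratio)))
  invisible(x)
}
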