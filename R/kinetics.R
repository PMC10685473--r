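#' Gravitational acceleration vector (m/s^2, internal lab frame, y up)
#' @keywords internal
GRAVITY <- c(0, -9.80665, 0)

#' Per-frame inertial state of one segment
#'
#' Converts a segment pose series into SI inertial quantities: centre of
#' mass halfway along the segment long axis, linear velocity and
#' acceleration by central finite differences at the marker rate, angular
#' velocity from orientation differences (the skew part of `Rdot t(R)`),
#' angular acceleration by differencing the angular velocity, and the
#' diagonal segment-frame inertia tensor `diag(m * (r_k * L)^2)`.
#'
#' @param pose a `segment_pose` (mm); must be gap-free over the trial
#' @param mass segment mass (kg)
#' @param radii length-3 radii of gyration as fractions of segment length
#' @return list with `com`, `vel`, `acc` (T x 3; m, m/s, m/s^2), `omega`,
#'   `alpha_ang` (T x 3, rad/s, rad/s^2, lab frame), `inertia` (length-3
#'   diagonal, kg m^2), `mass`
#' @export
segment_inertial_state <- function(pose, mass, radii) {
  if (any(pose$gap)) stop("segment_inertial_state: pose has gaps in the analysis window")
  nt <- dim(pose$R)[3L]
  if (nt < 5L) stop("segment_inertial_state: need at least 5 frames")
  L <- pose$length / 1000          # m
  com <- (pose$origin + t(vapply(seq_len(nt),
          function(t) pose$R[, 3L, t] * pose$length[t] / 2, numeric(3L)))) / 1000
  vel <- finite_difference(com, pose$rate, 1L)
  acc <- finite_difference(com, pose$rate, 2L)
  omega <- angular_velocity(pose$R, pose$rate)
  alpha_ang <- finite_difference(omega, pose$rate, 1L)
  L0 <- mean(L)
  inertia <- mass * (radii * L0)^2
  list(com = com, vel = vel, acc = acc, omega = omega, alpha_ang = alpha_ang,
       inertia = as.numeric(inertia), mass = mass)
}

# Joint-centre position series (mm): the ankle and Chopart centres are the
# inter-malleolar virtual marker (the midfoot frame origin); Lisfranc and
# 1st MTP centres are the distal segment frame origins.
joint_centre_series <- function(poses, joint) {
  switch(joint,
         ankle    = poses$midfoot$origin,
         chopart  = poses$midfoot$origin,
         lisfranc = poses$forefoot$origin,
         mtp1     = poses$hallux$origin,
         stop("unknown joint: ", joint))
}

# Distal segment sets for each joint of the chain.
distal_segments <- function(joint) {
  switch(joint,
         ankle    = c("hindfoot", "midfoot", "forefoot", "hallux"),
         chopart  = c("midfoot", "forefoot", "hallux"),
         lisfranc = c("forefoot", "hallux"),
         mtp1     = "hallux",
         stop("unknown joint: ", joint))
}

# Clinical component mapping for moments resolved in the proximal frame.
# Returns a 101x3 (or Tx3) matrix (sagittal, frontal, transverse) given the
# proximal-frame moment components. The shank frame's axes differ from the
# foot segments' (its y is anterior and z distal), hence the per-joint pick.
resolve_moment_components <- function(M_prox, joint, side, convention) {
  s <- clinical_sign(side)
  conv <- if (convention == "plantar") 1 else -1
  if (joint == "ankle") {
    out <- cbind(sagittal = -s[1L] * conv * M_prox[, 1L],
                 frontal  =  s[2L] * M_prox[, 2L],
                 transverse = -s[3L] * M_prox[, 3L])
  } else {
    out <- cbind(sagittal = -s[1L] * conv * M_prox[, 1L],
                 frontal  =  s[2L] * M_prox[, 3L],
                 transverse = s[3L] * M_prox[, 2L])
  }
  out
}

#' Newton-Euler inverse dynamics of the four-segment foot
#'
#' For each joint (ankle, Chopart, Lisfranc, 1st MTP) the net intersegmental
#' force and moment are computed from the free body containing every segment
#' distal to the joint. With a single force plate the full ground reaction
#' (force, centre of pressure and free vertical moment) is applied to each
#' joint's distal free body; segment inertial and gravitational effects are
#' included:
#' \deqn{F_J = \sum_{i} m_i (a_i - g) - F_{grf}}
#' \deqn{M_J = \sum_{i} [I_i \alpha_i + \omega_i \times I_i \omega_i +
#'   (r_i - c_J) \times m_i (a_i - g)] - (CoP - c_J) \times F_{grf} - T_z}
#' with the joint centre `c_J` at the distal segment's frame origin.
#' Moments are resolved in the proximal segment's frame, normalized by body
#' mass, and reported in the clinical convention selected by `convention`
#' (`"plantar"`: plantarflexion/inversion/internal-rotation positive, the
#' usual convention for foot joint moments; `"dorsi"`: dorsiflexion positive
#' instead, matching the angle convention).
#'
#' @param poses segment pose list from [pose_time_series()] (must include
#'   shank and the four foot segments)
#' @param anthro an `anthropometric_model`
#' @param fp a `force_plate_record` resampled to the marker rate
#' @param events optional `gait_events`; when supplied, moments and powers
#'   are also normalized to 101 points of the gait cycle
#' @param side `"right"` or `"left"`
#' @param convention `"plantar"` or `"dorsi"` (see above)
#' @return object of class `joint_kinetics_set`: per joint a list with
#'   `moment_lab` (T x 3, N m), `moment_prox` (T x 3, N m,
#'   proximal frame), `moment` (T or 101 x 3, N m/kg, clinical components),
#'   `power` (W/kg), `masked` (all FALSE; see [cpcross_mask()]),
#'   `crossing_index` (NA until masked)
#' @export
inverse_dynamics <- function(poses, anthro, fp, events = NULL,
                             side = "right", convention = c("plantar", "dorsi")) {
  convention <- match.arg(convention)
  segs <- c("hindfoot", "midfoot", "forefoot", "hallux")
  missing <- setdiff(c("shank", segs), names(poses))
  if (length(missing)) stop("inverse_dynamics: missing segment pose(s): ",
                            paste(missing, collapse = ", "))
  nt <- dim(poses[[1L]]$R)[3L]
  if (nrow(fp$force) != nt) {
    stop("inverse_dynamics: force record not at the marker rate (",
         nrow(fp$force), " vs ", nt, " frames)")
  }
  in_contact <- abs(fp$force[, 2L]) >= fp$contact_threshold
  if (any(in_contact & !fp$cop_valid)) {
    stop("inverse_dynamics: CoP missing during loaded stance frames")
  }

  states <- lapply(segs, function(sg) {
    segment_inertial_state(poses[[sg]], anthro$masses[[sg]],
                           anthro$radii[sg, ])
  })
  names(states) <- segs

  cop_m <- fp$cop / 1000
  grf <- fp$force
  grf[!in_contact, ] <- 0
  tz_vec <- cbind(0, fp$tz / 1000, 0)   # free vertical moment, N m about y
  tz_vec[!in_contact, ] <- 0

  joints <- foot_joints()
  out <- vector("list", nrow(joints))
  names(out) <- joints$joint
  for (i in seq_len(nrow(joints))) {
    jn <- joints$joint[i]
    child <- joints$child[i]
    parent <- joints$parent[i]
    cJ <- joint_centre_series(poses, jn) / 1000   # joint centre, m
    D <- distal_segments(jn)

    M <- matrix(0, nt, 3L)
    Fj <- matrix(0, nt, 3L)
    for (sg in D) {
      st <- states[[sg]]
      Rsg <- poses[[sg]]$R
      net <- sweep(st$acc, 2L, GRAVITY, `-`) * st$mass   # m(a - g)
      Fj <- Fj + net
      lever <- st$com - cJ
      M <- M + row_cross(lever, net)
      for (t in seq_len(nt)) {
        Rt <- Rsg[, , t]
        Ilab <- Rt %*% (st$inertia * t(Rt))   # R diag(I) R'
        M[t, ] <- M[t, ] + Ilab %*% st$alpha_ang[t, ] +
          cross3(st$omega[t, ], Ilab %*% st$omega[t, ])
      }
    }
    ext_lever <- cop_m - cJ
    ext_lever[!in_contact, ] <- 0
    M <- M - row_cross(ext_lever, grf) - tz_vec
    Fj <- Fj - grf

    omega_parent <- if (parent == "shank") {
      angular_velocity(poses$shank$R, poses$shank$rate)
    } else {
      states[[parent]]$omega
    }
    omega_rel <- states[[child]]$omega - omega_parent
    power <- rowSums(M * omega_rel) / anthro$body_mass

    M_prox <- t(vapply(seq_len(nt),
                       function(t) drop(crossprod(poses[[parent]]$R[, , t], M[t, ])),
                       numeric(3L)))
    clin <- resolve_moment_components(M_prox, jn, side, convention) / anthro$body_mass

    jk <- list(joint = jn, moment_lab = M, force_lab = Fj,
               moment_prox = M_prox, moment = clin, power = power,
               crossing_index = NA_real_, masked = rep(FALSE, nrow(clin)))
    out[[jn]] <- jk
  }

  if (!is.null(events)) {
    for (jn in names(out)) {
      out[[jn]]$moment <- normalize_gait_cycle(out[[jn]]$moment, events)
      colnames(out[[jn]]$moment) <- c("sagittal", "frontal", "transverse")
      out[[jn]]$power <- normalize_gait_cycle(out[[jn]]$power, events)
      out[[jn]]$masked <- rep(FALSE, 101L)
    }
  }
  structure(list(joints = out, events = events, convention = convention,
                 side = side, body_mass = anthro$body_mass),
            class = "joint_kinetics_set")
}

row_cross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Mass-normalized joint power
#'
#' `P = M . (omega_child - omega_parent) / body_mass`, with all inputs in a
#' common (lab) frame.
#'
#' @param moment T x 3 joint moment (N m)
#' @param omega_child,omega_parent T x 3 angular velocities (rad/s)
#' @param body_mass body mass (kg)
#' @return numeric vector of powers (W/kg)
#' @export
joint_power <- function(moment, omega_child, omega_parent, body_mass) {
  moment <- rbind(moment, deparse.level = 0)
  omega_child <- rbind(omega_child, deparse.level = 0)
  omega_parent <- rbind(omega_parent, deparse.level = 0)
  if (!all(dim(moment) == dim(omega_child)) ||
      !all(dim(moment) == dim(omega_parent))) {
    stop("joint_power: moment and angular-velocity series must be aligned")
  }
  drop(rowSums(moment * (omega_child - omega_parent)) / body_mass)
}

#' @export
print.joint_kinetics_set <- function(x, ...) {
  cat("<joint_kinetics_set> convention:", x$convention, " side:", x$side, "\n")
  for (jn in names(x$joints)) {
    j <- x$joints[[jn]]
    cat(sprintf("  %-9s peak |M| %.3f N m/kg, peak |P| %.3f W/kg%s\n", jn,
                max(abs(j$moment)), max(abs(j$power)),
                if (is.finite(j$crossing_index))
                  sprintf(", CoP crossing @ %d%%", j$crossing_index) else ""))
  }
  invisible(x)
}
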