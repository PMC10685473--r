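#' Brute-force free-body reference for joint moments
#'
#' A deliberately plain, frame-by-frame re-implementation of the
#' single-plate free-body solution, kept independent of the vectorized
#' production code in [inverse_dynamics()] (its own cross products, its own
#' finite differences, its own gravity handling). Used as the oracle in the
#' validation suite and to attach ground-truth kinetics to synthetic trials:
#' for every joint it sums, over the segments distal to the joint, the
#' inertial force `m*a`, minus gravity `m*g`, minus the ground reaction, and
#' takes moments about the joint centre including the rotational terms
#' `I*alpha + omega x I*omega` and the free vertical moment.
#'
#' @param poses segment pose list (shank plus the four foot segments)
#' @param anthro an `anthropometric_model`
#' @param fp a `force_plate_record` at the marker rate
#' @return named list per joint with `moment` (T x 3, N m, lab frame),
#'   `force` (T x 3, N) and `power` (T, W/kg)
#' @export
newton_euler_reference <- function(poses, anthro, fp) {
  cp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  segs <- c("hindfoot", "midfoot", "forefoot", "hallux")
  nt <- dim(poses$hindfoot$R)[3]
  rate <- poses$hindfoot$rate
  dt <- 1 / rate
  grav <- c(0, -9.80665, 0)

  # per-segment kinematics, all in SI
  seg_state <- list()
  for (sg in segs) {
    p <- poses[[sg]]
    com <- matrix(0, nt, 3)
    for (t in 1:nt) {
      com[t, ] <- (p$origin[t, ] + p$R[, 3, t] * p$length[t] / 2) / 1000
    }
    acc <- matrix(0, nt, 3)
    for (t in 1:nt) {
      if (t == 1 || t == nt) {
        tt <- min(max(t, 2), nt - 1)
      } else tt <- t
      acc[t, ] <- (com[tt + 1, ] - 2 * com[tt, ] + com[tt - 1, ]) / dt^2
    }
    om <- matrix(0, nt, 3)
    for (t in 1:nt) {
      if (t == 1) {
        S <- ((p$R[, , 2] - p$R[, , 1]) / dt) %*% t(p$R[, , 1])
      } else if (t == nt) {
        S <- ((p$R[, , nt] - p$R[, , nt - 1]) / dt) %*% t(p$R[, , nt])
      } else {
        S <- ((p$R[, , t + 1] - p$R[, , t - 1]) / (2 * dt)) %*% t(p$R[, , t])
      }
      S <- (S - t(S)) / 2
      om[t, ] <- c(S[3, 2], S[1, 3], S[2, 1])
    }
    alp <- matrix(0, nt, 3)
    for (t in 1:nt) {
      if (t == 1) alp[t, ] <- (om[2, ] - om[1, ]) / dt
      else if (t == nt) alp[t, ] <- (om[nt, ] - om[nt - 1, ]) / dt
      else alp[t, ] <- (om[t + 1, ] - om[t - 1, ]) / (2 * dt)
    }
    m <- anthro$masses[[sg]]
    Idiag <- m * (anthro$radii[sg, ] * mean(p$length) / 1000)^2
    seg_state[[sg]] <- list(com = com, acc = acc, om = om, alp = alp,
                            m = m, Idiag = Idiag)
  }

  shank_om <- matrix(0, nt, 3)
  for (t in 1:nt) {
    if (t == 1) {
      S <- ((poses$shank$R[, , 2] - poses$shank$R[, , 1]) / dt) %*% t(poses$shank$R[, , 1])
    } else if (t == nt) {
      S <- ((poses$shank$R[, , nt] - poses$shank$R[, , nt - 1]) / dt) %*% t(poses$shank$R[, , nt])
    } else {
      S <- ((poses$shank$R[, , t + 1] - poses$shank$R[, , t - 1]) / (2 * dt)) %*% t(poses$shank$R[, , t])
    }
    S <- (S - t(S)) / 2
    shank_om[t, ] <- c(S[3, 2], S[1, 3], S[2, 1])
  }

  chain <- list(ankle = segs, chopart = segs[2:4], lisfranc = segs[3:4],
                mtp1 = segs[4])
  centre_seg <- c(ankle = "midfoot", chopart = "midfoot",
                  lisfranc = "forefoot", mtp1 = "hallux")
  child_of <- c(ankle = "hindfoot", chopart = "midfoot",
                lisfranc = "forefoot", mtp1 = "hallux")
  parent_of <- c(ankle = "shank", chopart = "hindfoot",
                 lisfranc = "midfoot", mtp1 = "forefoot")
  out <- list()
  for (jn in names(chain)) {
    child <- child_of[[jn]]
    Mj <- matrix(0, nt, 3)
    Fjm <- matrix(0, nt, 3)
    Pw <- numeric(nt)
    for (t in 1:nt) {
      cJ <- poses[[centre_seg[[jn]]]]$origin[t, ] / 1000
      Fsum <- c(0, 0, 0)
      Msum <- c(0, 0, 0)
      for (sg in chain[[jn]]) {
        st <- seg_state[[sg]]
        f_in <- st$m * (st$acc[t, ] - grav)
        Fsum <- Fsum + f_in
        Msum <- Msum + cp(st$com[t, ] - cJ, f_in)
        Rt <- poses[[sg]]$R[, , t]
        Iw <- Rt %*% diag(st$Idiag) %*% t(Rt)
        Msum <- Msum + as.numeric(Iw %*% st$alp[t, ]) +
          cp(st$om[t, ], as.numeric(Iw %*% st$om[t, ]))
      }
      loaded <- abs(fp$force[t, 2]) >= fp$contact_threshold
      if (loaded) {
        grf <- fp$force[t, ]
        copm <- fp$cop[t, ] / 1000
        Fsum <- Fsum - grf
        Msum <- Msum - cp(copm - cJ, grf) - c(0, fp$tz[t] / 1000, 0)
      }
      Mj[t, ] <- Msum
      Fjm[t, ] <- Fsum
      om_par <- if (parent_of[[jn]] == "shank") shank_om[t, ] else
        seg_state[[parent_of[[jn]]]]$om[t, ]
      Pw[t] <- sum(Msum * (seg_state[[child]]$om[t, ] - om_par)) / anthro$body_mass
    }
    out[[jn]] <- list(moment = Mj, force = Fjm, power = Pw)
  }
  out
}
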