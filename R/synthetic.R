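#' Default joint waveform templates for the synthetic walking trial
#'
#' Each joint/plane excursion is a periodic cubic spline through knot points
#' over the gait cycle (0 = heel strike, toe off at the stance fraction),
#' linearly rescaled so the excursion's maximum and minimum over the cycle
#' equal the targets `hi` and `lo` (degrees). The default targets reproduce
#' the ranges of motion reported for healthy adults with this model
#' (hindfoot sagittal ~26.3 deg, midfoot sagittal ~6.5 deg, forefoot
#' sagittal ~14.2 deg, hallux sagittal ~37.3 deg, hallux
#' abduction/adduction ~11.6 deg). The frontal-plane (long-axis twist)
#' excursions of the forefoot and hallux are held constant: the model's
#' skeleton definitions take those segments' plane markers from the parent
#' segment, so an independent twist of the distal segment is not observable
#' by the constructed frames (see the methods vignette).
#'
#' @return nested list `waveforms[[joint]][[plane]]` with `knots`, `hi`,
#'   `lo`
#' @export
default_waveforms <- function() {
  k <- function(...) {
    m <- matrix(c(...), ncol = 2L, byrow = TRUE)
    colnames(m) <- c("p", "y")
    m
  }
  list(
    ankle = list(
      sagittal   = list(knots = k(0, 0, 0.12, -5, 0.45, 7.7, 0.62, -18.6, 0.82, 2, 1, 0),
                        hi = 7.65, lo = -18.65),
      frontal    = list(knots = k(0, 0, 0.2, -2, 0.55, 4.5, 0.78, 1, 1, 0),
                        hi = 4.53, lo = -2.03),
      transverse = list(knots = k(0, 0, 0.3, -2.4, 0.55, 0.3, 0.8, -1, 1, 0),
                        hi = 0.28, lo = -2.44)
    ),
    chopart = list(
      sagittal   = list(knots = k(0, 0, 0.3, 0.4, 0.52, 0.8, 0.68, -5.7, 0.85, -1.5, 1, 0),
                        hi = 0.77, lo = -5.69),
      frontal    = list(knots = k(0, 0, 0.3, -1, 0.55, -3.7, 0.8, 0.3, 1, 0),
                        hi = 0.27, lo = -3.66),
      transverse = list(knots = k(0, 0, 0.3, 2.1, 0.6, -1.6, 0.85, 0.5, 1, 0),
                        hi = 2.10, lo = -1.61)
    ),
    lisfranc = list(
      sagittal   = list(knots = k(0, 0, 0.2, -2, 0.55, 8.2, 0.7, -5.9, 0.88, 0, 1, 0),
                        hi = 8.23, lo = -5.95),
      frontal    = list(knots = NULL, hi = 0, lo = 0),
      transverse = list(knots = k(0, 0, 0.35, 5.5, 0.65, -2, 0.9, 1, 1, 0),
                        hi = 5.50, lo = -1.98)
    ),
    mtp1 = list(
      sagittal   = list(knots = k(0, 8, 0.25, 4, 0.45, 0, 0.62, 37, 0.8, 12, 1, 8),
                        hi = 38.47, lo = 1.18),
      frontal    = list(knots = NULL, hi = 0, lo = 0),
      transverse = list(knots = k(0, 0, 0.4, 0.3, 0.63, -11.4, 0.85, -3, 1, 0),
                        hi = 0.27, lo = -11.37)
    )
  )
}

# Turn a waveform template into a function of cycle fraction p in [0, 1).
waveform_function <- function(wf) {
  if (is.null(wf$knots) || wf$hi == wf$lo) {
    return(function(p) rep(wf$hi, length(p)))
  }
  f <- stats::splinefun(wf$knots[, 1L], wf$knots[, 2L], method = "periodic")
  pf <- seq(0, 1, length.out = 801L)
  fv <- f(pf)
  lo0 <- min(fv); hi0 <- max(fv)
  function(p) wf$lo + (wf$hi - wf$lo) * (f(p %% 1) - lo0) / (hi0 - lo0)
}

#' Neutral marker geometry of the synthetic foot
#'
#' Marker positions (mm) of a right foot standing at the lab origin, foot
#' pointing along +x. Two placement rules tie the geometry to the skeleton
#' definitions so that constructed frames reproduce prescribed joint
#' rotations exactly: the navicular/cuboid pair straddles the midpoint
#' V_MidNC along the midfoot frame's medio-lateral axis (tilted so the
#' navicular sits higher than the cuboid, as in the real tarsus), and the
#' 2nd/3rd metatarsal marker lies along the forefoot frame's medio-lateral
#' axis from the first metatarsal head. The metatarsal-head pair straddles
#' its midpoint V_15MTH. The left side is the mirror image (z negated).
#'
#' @param side `"right"` or `"left"`
#' @return named list of 3-vectors (mm)
#' @export
neutral_geometry <- function(side = "right") {
  g <- list(
    KNL = c(0, 470, -55), KNM = c(0, 470, 55),
    MM = c(0, 75, 40), LM = c(0, 70, -40),
    TC = c(-52, 78, 0), BC = c(-60, 25, 0),
    TH = c(45, 55, 0)
  )
  ajc <- (g$MM + g$LM) / 2
  z_mf <- unit3(g$TH - ajc)
  # midfoot ML axis, tilted ~25 deg so the navicular ends up above the cuboid
  x_mf <- c(0, -0.42, -0.908)
  x_mf <- unit3(x_mf - sum(x_mf * z_mf) * z_mf)
  y_mf <- cross3(z_mf, x_mf)
  midnc <- ajc + 44 * z_mf - 30 * y_mf
  g$NV <- midnc - 30 * x_mf
  g$CB <- midnc + 30 * x_mf
  cff <- c(95, 28, 0)
  f_ff <- build_segment_frame(midnc, cff, g$NV, rz = -90)
  x_ff <- f_ff$R[, 1L]
  g$MTH1 <- cff + c(3, -1, 35)
  g$MTH5 <- cff - c(3, -1, 35)
  g$MTH23 <- g$MTH1 + 35 * x_ff
  g$HLX <- g$MTH1 + c(61.4, -8.9, 0)
  if (side == "left") g <- lapply(g, function(v) v * c(1, 1, -1))
  g
}

#' Specification of a synthetic walking trial
#'
#' @param waveforms joint excursion templates, see [default_waveforms()]
#' @param stance_fraction fraction of the gait cycle in stance (default 0.60)
#' @param cadence steps per minute (default 112; the stride period is
#'   `120/cadence` seconds)
#' @param walking_speed forward progression speed (m/s)
#' @param body_mass body mass (kg)
#' @param marker_noise_sd isotropic marker noise SD per coordinate (mm)
#' @param seed RNG seed for the noise
#' @param side `"right"` or `"left"`
#' @param marker_rate,force_rate sampling rates (Hz)
#' @param geometry neutral marker geometry, see [neutral_geometry()]
#' @return object of class `synthetic_trial_spec`
#' @export
synthetic_trial_spec <- function(waveforms = default_waveforms(),
                                 stance_fraction = 0.60,
                                 cadence = 112,
                                 walking_speed = 1.22,
                                 body_mass = 64,
                                 marker_noise_sd = 0,
                                 seed = 1L,
                                 side = "right",
                                 marker_rate = 60,
                                 force_rate = 1200,
                                 geometry = NULL) {
  if (!(stance_fraction > 0 && stance_fraction < 1)) {
    stop("synthetic_trial_spec: stance_fraction must lie in (0, 1)")
  }
  if (marker_noise_sd < 0) stop("synthetic_trial_spec: marker_noise_sd must be >= 0")
  if (is.null(geometry)) geometry <- neutral_geometry(side)
  structure(
    list(waveforms = waveforms, stance_fraction = stance_fraction,
         cadence = cadence, walking_speed = walking_speed,
         body_mass = body_mass, marker_noise_sd = marker_noise_sd,
         seed = as.integer(seed), side = side, marker_rate = marker_rate,
         force_rate = force_rate, geometry = geometry),
    class = "synthetic_trial_spec"
  )
}

#' Healthy-adult default trial specification
#'
#' The default waveforms, a 0.60 stance fraction, cadence 112 steps/min,
#' 1.22 m/s walking speed and 64 kg body mass; the resulting trial shows
#' the healthy ranges of motion of the default templates and a medial
#' longitudinal arch that compresses through stance with its minimum
#' shortly before toe off.
#'
#' @param seed RNG seed
#' @param marker_noise_sd marker noise SD (mm), default 0
#' @return a `synthetic_trial_spec`
#' @export
healthy_default_spec <- function(seed = 1L, marker_noise_sd = 0) {
  synthetic_trial_spec(seed = seed, marker_noise_sd = marker_noise_sd)
}

# Double-hump vertical GRF profile on stance fraction tau in [0, 1]:
# a half-sine loading envelope modulated by a second harmonic (peaks near
# 30% and 70% of stance, valley at midstance), with a steep linear rise at
# contact as in real heel strikes, scaled so the stance-phase mean is 1
# (body weight).
grf_profile <- function(tau) {
  shape <- function(u) sin(pi * u) * (0.6 + 0.4 * sin(2 * pi * u)^2)
  # stance mean of the raw shape: int sin = 2/pi; int sin*sin^2(2.) computed
  # once on a fine grid
  u <- seq(0, 1, length.out = 4001L)
  scale <- 1 / mean(shape(u))
  inside <- tau >= 0 & tau <= 1
  y <- numeric(length(tau))
  y[inside] <- scale * shape(tau[inside])
  y
}

#' Generate a synthetic walking trial
#'
#' Forward model of a rigid four-segment foot: the shank translates and
#' tilts through the gait cycle, each joint follows its prescribed x-z-y
#' Cardan waveform (neutral posture plus excursion), and every physical
#' marker rides rigidly on its segment. The vertical ground reaction is a
#' double-hump profile whose stance-phase mean equals body weight; the
#' centre of pressure travels from under the heel (BC) to under the hallux
#' across stance. Optional isotropic marker noise is added after posing
#' (seeded, restoring the caller's RNG state).
#'
#' @param spec a [synthetic_trial_spec()]
#' @return list of class `synthetic_trial` with elements `traj`
#'   (`marker_trajectories`, 60 Hz), `fp` (`force_plate_record`, 1200 Hz),
#'   `truth` (ground truth: `angles` [101 x 3 per joint, clinical degrees],
#'   `events`, `cycle_frames`, `stance_fraction`, `poses` [true segment
#'   poses at marker frames], `neutral` [neutral clinical angles], `mla`,
#'   `cop101`) and `spec`
#' @export
generate_trial <- function(spec = healthy_default_spec()) {
  side <- spec$side
  s <- clinical_sign(side)
  geom <- spec$geometry
  defs <- segment_definitions(side)
  registry <- marker_set_registry(side)

  # neutral frames from one static frame of the geometry
  traj0 <- marker_trajectories(lapply(geom, function(v) matrix(v, 1L, 3L)), spec$marker_rate)
  traj0 <- compute_virtual_markers(traj0, registry)
  poses0 <- pose_time_series(traj0, defs)
  R0 <- lapply(poses0, function(p) p$R[, , 1L])
  joints <- foot_joints()
  w0 <- lapply(seq_len(nrow(joints)), function(i) {
    s * cardan_xzy(crossprod(R0[[joints$parent[i]]], R0[[joints$child[i]]]))
  })
  names(w0) <- joints$joint

  wf_fun <- lapply(spec$waveforms, function(jw) lapply(jw, waveform_function))

  # timing
  T_cycle <- 120 / spec$cadence
  t_hs <- (round(0.3 * spec$marker_rate) + 0.5) / spec$marker_rate
  duration <- t_hs + T_cycle + 0.3
  nt <- floor(duration * spec$marker_rate) + 1L
  tt <- (seq_len(nt) - 1L) / spec$marker_rate
  phase <- ((tt - t_hs) / T_cycle) %% 1
  stride_mm <- spec$walking_speed * T_cycle * 1000

  ajc0 <- (geom$MM + geom$LM) / 2
  cyc <- (tt - t_hs) / T_cycle              # signed cycle count for translation
  # forward progression: monotone, slow around heel strike, fast in swing
  ajc_t <- cbind(stride_mm * (cyc - 0.14 * sin(2 * pi * cyc)),
                 10 * sin(4 * pi * cyc + 0.5), 4 * sin(2 * pi * cyc))
  ajc_t <- sweep(ajc_t, 2L, ajc0, `+`)
  shank_tilt <- 16 * sin(2 * pi * phase + 0.4)

  # joint rotation series (clinical -> raw)
  wtot <- lapply(joints$joint, function(jn) {
    cbind(alpha_x = w0[[jn]]["alpha_x"] + wf_fun[[jn]]$sagittal(phase),
          beta_z  = w0[[jn]]["beta_z"]  + wf_fun[[jn]]$frontal(phase),
          gamma_y = w0[[jn]]["gamma_y"] + wf_fun[[jn]]$transverse(phase))
  })
  names(wtot) <- joints$joint

  # pose the chain and place markers
  seg_of <- list(
    shank = c("KNL", "KNM", "MM", "LM"),
    hindfoot = c("TC", "BC"),
    midfoot = c("TH", "NV", "CB"),
    forefoot = c("MTH1", "MTH5", "MTH23"),
    hallux = "HLX"
  )
  midnc0 <- (geom$NV + geom$CB) / 2
  positions <- lapply(geom, function(v) matrix(NA_real_, nt, 3L))
  Rtrue <- lapply(R0, function(R) array(NA_real_, c(3L, 3L, nt)))
  otrue <- stats::setNames(
    lapply(1:5, function(i) matrix(NA_real_, nt, 3L)),
    c("shank", "hindfoot", "midfoot", "forefoot", "hallux"))

  for (t in seq_len(nt)) {
    Rsh <- rot_z(shank_tilt[t]) %*% R0$shank
    Dsh <- Rsh %*% t(R0$shank)
    pv_ajc <- ajc_t[t, ]
    place <- function(labels, Dseg, pivot_pos, pivot0) {
      for (lb in labels) {
        positions[[lb]][t, ] <<- pivot_pos + Dseg %*% (geom[[lb]] - pivot0)
      }
    }
    place(seg_of$shank, Dsh, pv_ajc, ajc0)
    Rhf <- Rsh %*% cardan_compose(s[1L] * wtot$ankle[t, 1L], s[2L] * wtot$ankle[t, 2L],
                                  s[3L] * wtot$ankle[t, 3L])
    Dhf <- Rhf %*% t(R0$hindfoot)
    place(seg_of$hindfoot, Dhf, pv_ajc, ajc0)
    Rmf <- Rhf %*% cardan_compose(s[1L] * wtot$chopart[t, 1L], s[2L] * wtot$chopart[t, 2L],
                                  s[3L] * wtot$chopart[t, 3L])
    Dmf <- Rmf %*% t(R0$midfoot)
    place(seg_of$midfoot, Dmf, pv_ajc, ajc0)
    midnc_t <- pv_ajc + Dmf %*% (midnc0 - ajc0)
    Rff <- Rmf %*% cardan_compose(s[1L] * wtot$lisfranc[t, 1L], s[2L] * wtot$lisfranc[t, 2L],
                                  s[3L] * wtot$lisfranc[t, 3L])
    Dff <- Rff %*% t(R0$forefoot)
    place(seg_of$forefoot, Dff, midnc_t, midnc0)
    mth1_t <- positions$MTH1[t, ]
    Rhx <- Rff %*% cardan_compose(s[1L] * wtot$mtp1[t, 1L], s[2L] * wtot$mtp1[t, 2L],
                                  s[3L] * wtot$mtp1[t, 3L])
    Dhx <- Rhx %*% t(R0$hallux)
    place(seg_of$hallux, Dhx, mth1_t, geom$MTH1)
    Rtrue$shank[, , t] <- Rsh; Rtrue$hindfoot[, , t] <- Rhf
    Rtrue$midfoot[, , t] <- Rmf; Rtrue$forefoot[, , t] <- Rff
    Rtrue$hallux[, , t] <- Rhx
    otrue$shank[t, ] <- (positions$KNL[t, ] + positions$KNM[t, ]) / 2
    otrue$hindfoot[t, ] <- positions$BC[t, ]
    otrue$midfoot[t, ] <- pv_ajc
    otrue$forefoot[t, ] <- midnc_t
    otrue$hallux[t, ] <- mth1_t
  }

  # marker noise
  if (spec$marker_noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed)
    for (lb in names(positions)) {
      positions[[lb]] <- positions[[lb]] +
        matrix(stats::rnorm(3L * nt, 0, spec$marker_noise_sd), nt, 3L)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }
  traj <- marker_trajectories(positions, spec$marker_rate)

  # force plate at force_rate
  nf <- floor(duration * spec$force_rate) + 1L
  tf <- (seq_len(nf) - 1L) / spec$force_rate
  tauf <- (tf - t_hs) / (spec$stance_fraction * T_cycle)
  bw <- spec$body_mass * 9.80665
  fy <- bw * grf_profile(tauf)
  fx <- -0.15 * bw * sin(2 * pi * pmin(pmax(tauf, 0), 1)) * (tauf >= 0 & tauf <= 1)
  fz <- 0.05 * bw * sin(pi * pmin(pmax(tauf, 0), 1)) * (tauf >= 0 & tauf <= 1)
  tzf <- 800 * sin(2 * pi * pmin(pmax(tauf, 0), 1)) * (tauf >= 0 & tauf <= 1)
  # CoP: from under BC to under HLX, linear in stance time, riding on the foot
  bc_f <- apply(positions$BC, 2L, function(cl) stats::approx(tt, cl, xout = tf, rule = 2L)$y)
  hx_f <- apply(positions$HLX, 2L, function(cl) stats::approx(tt, cl, xout = tf, rule = 2L)$y)
  gmix <- pmin(pmax(tauf, 0), 1)
  cop <- bc_f * (1 - gmix) + hx_f * gmix
  cop[, 2L] <- 0
  cop[fy < 20, ] <- NA_real_
  fp <- force_plate_record(cbind(fx, fy, fz), cop, tzf, spec$force_rate)

  # ground truth ---------------------------------------------------------
  fy_frames <- bw * grf_profile((tt - t_hs) / (spec$stance_fraction * T_cycle))
  hs_f <- which(fy_frames >= 20)[1L]
  to_f <- which(fy_frames < 15 & seq_len(nt) > hs_f)[1L]
  ce_f <- hs_f + (to_f - hs_f) / 0.60
  ev <- structure(list(heel_strike = hs_f, toe_off = to_f, cycle_end = ce_f,
                       stance_fraction = (to_f - hs_f) / (ce_f - hs_f),
                       extrapolated = TRUE),
                  class = "gait_events")
  grid <- hs_f + (0:100) / 100 * (ce_f - hs_f)
  angles <- lapply(wtot, function(w) {
    out <- apply(w, 2L, function(col) stats::approx(seq_len(nt), col, xout = grid)$y)
    colnames(out) <- c("alpha_x", "beta_z", "gamma_y")
    out
  })
  seg_len <- c(
    shank = sqrt(sum((ajc0 - (geom$KNL + geom$KNM) / 2)^2)),
    hindfoot = sqrt(sum((ajc0 - geom$BC)^2)),
    midfoot = sqrt(sum((geom$TH - ajc0)^2)),
    forefoot = sqrt(sum(((geom$MTH1 + geom$MTH5) / 2 - midnc0)^2)),
    hallux = sqrt(sum((geom$HLX - geom$MTH1)^2))
  )
  poses_true <- lapply(names(Rtrue), function(nm) {
    structure(list(name = nm, R = Rtrue[[nm]], origin = otrue[[nm]],
                   length = rep(seg_len[[nm]], nt),
                   gap = rep(FALSE, nt), rate = spec$marker_rate),
              class = "segment_pose")
  })
  names(poses_true) <- names(Rtrue)

  mla_true <- mla_ratio(positions$BC, positions$MTH1, positions$NV)
  truth <- list(
    angles = angles, neutral = w0, events = ev,
    cycle_frames = T_cycle * spec$marker_rate,
    stance_fraction = spec$stance_fraction,
    poses = poses_true,
    mla = mla_true,
    t_hs = t_hs, T_cycle = T_cycle
  )
  structure(list(traj = traj, fp = fp, truth = truth, spec = spec),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat("<synthetic_trial> side:", x$spec$side, "\n  markers:",
      n_frames(x$traj), "frames @", x$traj$rate, "Hz;  force:",
      nrow(x$fp$force), "samples @", x$fp$rate, "Hz\n  stance fraction:",
      x$truth$stance_fraction, " noise SD:", x$spec$marker_noise_sd, "mm\n")
  invisible(x)
}
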