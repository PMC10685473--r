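test_that("the zero-phase Butterworth has unit DC gain, a flat passband and a deep stopband", {
  const <- rep(3.7, 200)
  expect_lt(max(abs(butterworth_lowpass(const, 6, 60) - const)), 1e-9)

  tt <- (0:599) / 60
  pass <- sin(2 * pi * 1 * tt)
  out <- butterworth_lowpass(pass, 6, 60)
  mid <- 150:450
  expect_lt(max(abs(out[mid] - pass[mid])), 0.01)

  tt2 <- (0:599) / 120  # 25 Hz sine sampled at 120 Hz
  stopb <- sin(2 * pi * 25 * tt2)
  out2 <- butterworth_lowpass(stopb, 6, 120)
  expect_lt(max(abs(out2[150:450])), 0.01)

  expect_error(butterworth_lowpass(rep(1, 5), 6, 60), "too short")
  expect_error(butterworth_lowpass(rep(1, 100), 40, 60), "cutoff")
})

test_that("x-z-y Cardan extraction inverts single-axis rotations", {
  expect_equal(unname(cardan_xzy(diag(3))), c(0, 0, 0))
  expect_equal(unname(cardan_xzy(rot_x(20))), c(20, 0, 0), tolerance = 1e-12)
  expect_equal(unname(cardan_xzy(rot_z(-5))), c(0, -5, 0), tolerance = 1e-12)
  expect_equal(unname(cardan_xzy(rot_y(7))), c(0, 0, 7), tolerance = 1e-12)
})

test_that("compose-then-extract recovers random gimbal-safe angle triples", {
  set.seed(3)
  worst <- 0
  for (i in 1:1000) {
    ang <- c(runif(1, -170, 170), runif(1, -60, 60), runif(1, -170, 170))
    back <- cardan_xzy(cardan_compose(ang[1], ang[2], ang[3]))
    worst <- max(worst, max(abs(back - ang)))
  }
  expect_lt(worst, 1e-9)
})

test_that("cardan extraction warns near gimbal lock and rejects non-rotations", {
  expect_warning(cardan_xzy(cardan_compose(10, 89.95, 5)), "gimbal")
  expect_error(cardan_xzy(matrix(1:9 / 10, 3, 3)), "orthonormal")
})

test_that("relative rotation is identity for self, child for lab parent, and frame-invariant", {
  tr <- cached_trial(seed = 1)
  poses <- pose_time_series(compute_virtual_markers(tr$traj),
                            segment_definitions("right"))
  rel_self <- relative_rotation(poses$midfoot, poses$midfoot)
  expect_equal(rel_self[, , 5], diag(3), tolerance = 1e-12)

  lab <- poses$shank
  lab$R[] <- array(diag(3), dim(lab$R))
  rel_lab <- relative_rotation(poses$hindfoot, lab)
  expect_equal(rel_lab[, , 5], poses$hindfoot$R[, , 5], tolerance = 1e-12)

  set.seed(5)
  Q <- random_rotation()
  child2 <- poses$hindfoot; parent2 <- poses$shank
  for (t in seq_len(dim(child2$R)[3])) {
    child2$R[, , t] <- Q %*% child2$R[, , t]
    parent2$R[, , t] <- Q %*% parent2$R[, , t]
  }
  expect_equal(relative_rotation(child2, parent2)[, , 8],
               relative_rotation(poses$hindfoot, poses$shank)[, , 8],
               tolerance = 1e-12)
})

test_that("MLA geometry: right triangle, collinear case, rigid and scale invariance", {
  m <- mla_ratio(c(0, 0, 0), c(4, 0, 0), c(1, 3, 0))
  expect_equal(m$length, 4)
  expect_equal(m$height, 3)
  expect_equal(m$ratio, 0.75)

  m0 <- mla_ratio(c(0, 0, 0), c(4, 0, 0), c(2, 0, 0))
  expect_equal(m0$height, 0)
  expect_equal(m0$ratio, 0)

  expect_error(mla_ratio(c(1, 1, 1), c(1, 1, 1), c(0, 0, 0)), "coincide")

  set.seed(9)
  bc <- c(-60, 25, 0); mt <- c(98, 28, 35); nv <- c(38, 50, 28)
  r0 <- mla_ratio(bc, mt, nv)$ratio
  for (i in 1:20) {
    R <- random_rotation(); tr <- rnorm(3) * 200; s <- runif(1, 0.2, 5)
    r1 <- mla_ratio(s * drop(R %*% bc + tr), s * drop(R %*% mt + tr),
                    s * drop(R %*% nv + tr))$ratio
    expect_equal(r1, r0, tolerance = 1e-12)
  }
})

test_that("gait events are detected from a rectangular pulse and absent contact errors", {
  n <- 100L
  fy <- numeric(n); fy[10:69] <- 600
  fp <- force_plate_record(cbind(0, fy, 0), matrix(0, n, 3L), rate = 60)
  ev <- detect_gait_events(fp, threshold = 20)
  expect_equal(ev$heel_strike, 10L)
  expect_equal(ev$toe_off, 70L)
  expect_equal(ev$stance_fraction, 0.6, tolerance = 1e-12)

  fp0 <- force_plate_record(matrix(0, n, 3L), matrix(0, n, 3L), rate = 60)
  expect_error(detect_gait_events(fp0), "no contact")
})

test_that("synthetic stance fraction is recovered within 0.02", {
  tr <- cached_trial(seed = 1)
  fp60 <- resample_force_to_markers(tr$fp, 60)
  ev <- detect_gait_events(fp60)
  achieved <- (ev$toe_off - ev$heel_strike) / tr$truth$cycle_frames
  expect_lt(abs(achieved - 0.60), 0.02)
})

test_that("gait-cycle normalization emits exactly 101 samples and is exact on ramps", {
  ev <- structure(list(heel_strike = 3L, toe_off = 55L, cycle_end = 90L,
                       stance_fraction = 0.6, extrapolated = FALSE),
                  class = "gait_events")
  ramp <- seq(0, 10, length.out = 120)
  out <- normalize_gait_cycle(ramp, ev)
  expect_length(out, 101L)
  expect_equal(out, seq(ramp[3], ramp[90], length.out = 101), tolerance = 1e-12)
  expect_equal(out[1], ramp[3])
  expect_equal(out[101], ramp[90])

  # an 87-frame stride still yields 101 points
  ev87 <- structure(list(heel_strike = 1L, toe_off = 53L, cycle_end = 88L,
                         stance_fraction = 0.6, extrapolated = FALSE),
                    class = "gait_events")
  expect_length(normalize_gait_cycle(rnorm(88), ev87), 101L)

  const <- rep(2.5, 120)
  expect_equal(normalize_gait_cycle(const, ev), rep(2.5, 101))

  gapped <- ramp; gapped[30] <- NA
  expect_error(normalize_gait_cycle(gapped, ev), "gaps")
})

test_that("the full pipeline recovers prescribed waveforms exactly on noise-free data", {
  tr <- cached_trial(seed = 1)
  kin <- cached_kinematics(seed = 1, cutoff = NULL)
  for (jn in names(kin$angles)) {
    expect_lt(max(abs(kin$angles[[jn]] - tr$truth$angles[[jn]])), 1e-6)
    expect_equal(nrow(kin$angles[[jn]]), 101L)
  }
})

test_that("marker noise degrades recovery gracefully under the 6 Hz filter", {
  tr <- cached_trial(seed = 1, noise = 2)
  kin <- cached_kinematics(seed = 1, noise = 2, cutoff = 6)
  pooled <- sqrt(mean(unlist(lapply(names(kin$angles), function(jn)
    (kin$angles[[jn]] - tr$truth$angles[[jn]])^2))))
  # noise-limited by the plane-marker levers of this marker set; see the
  # methods vignette for the error budget
  expect_lt(pooled, 2.5)
})

test_that("a static neutral trial yields constant angle curves", {
  traj <- static_traj(n = 120L)
  fp <- static_force(n = 120L)
  cfg <- trial_config(filter_cutoff = NULL)
  kin <- joint_angle_pipeline(traj, fp, cfg, events = static_events())
  for (jn in names(kin$angles)) {
    expect_lt(max(apply(kin$angles[[jn]], 2, function(v) diff(range(v)))), 1e-9)
  }
  expect_lt(diff(range(kin$mla$ratio)), 1e-12)
})

test_that("whole-pipeline output is invariant to a rotation of the lab frame", {
  tr <- cached_trial(seed = 1)
  cfg <- trial_config(filter_cutoff = NULL)
  kin <- cached_kinematics(seed = 1, cutoff = NULL)
  traj2 <- tr$traj
  yaw <- rot_y(30)  # rotate the walkway about the vertical
  for (lb in traj2$labels) {
    traj2$positions[[lb]] <- t(yaw %*% t(traj2$positions[[lb]]))
  }
  fp2 <- tr$fp
  fp2$force <- t(yaw %*% t(fp2$force))
  fp2$cop <- t(yaw %*% t(fp2$cop))
  kin2 <- joint_angle_pipeline(traj2, fp2, cfg)
  for (jn in names(kin$angles)) {
    expect_lt(max(abs(kin2$angles[[jn]] - kin$angles[[jn]])), 1e-9)
  }
  expect_equal(kin2$mla$ratio, kin$mla$ratio, tolerance = 1e-12)
})

test_that("left-side trials mirror right-side clinical angles exactly", {
  kr <- cached_kinematics(seed = 4, side = "right", cutoff = NULL)
  kl <- cached_kinematics(seed = 4, side = "left", cutoff = NULL)
  for (jn in names(kr$angles)) {
    expect_lt(max(abs(kr$angles[[jn]] - kl$angles[[jn]])), 1e-9)
  }
})

test_that("the MLA ratio dips in late stance and stays in the healthy band", {
  kin <- cached_kinematics(seed = 1, cutoff = NULL)
  ratio <- kin$mla$ratio
  nadir <- which.min(ratio) - 1L
  to <- round(100 * kin$events$stance_fraction)
  expect_gt(nadir, 25)
  expect_lt(nadir, to)
  expect_gt(min(ratio), 0.10)
  expect_lt(max(ratio), 0.20)
  # rebounds after toe off
  expect_gt(ratio[81], ratio[nadir + 1L])
})
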