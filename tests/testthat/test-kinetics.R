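test_that("foot mass is apportioned by the volume rule and conserved", {
  unit_foot <- list(foot_mass_fraction = 1)
  a0 <- build_anthropometrics(1, c(unit_foot, list(toes_volume_fraction = 0)))
  expect_equal(unname(a0$masses), c(0.5, 0.25, 0.25, 0))

  a8 <- build_anthropometrics(1, c(unit_foot, list(toes_volume_fraction = 0.08)))
  expect_equal(unname(a8$masses), c(0.46, 0.23, 0.23, 0.08), tolerance = 1e-12)

  set.seed(2)
  for (i in 1:20) {
    bm <- runif(1, 40, 110); tau <- runif(1, 0.01, 0.49)
    a <- build_anthropometrics(bm, list(toes_volume_fraction = tau))
    expect_lt(abs(sum(a$masses) - a$foot_mass), 1e-12)
    expect_equal(unname(a$masses[["hindfoot"]]), 0.5 * (1 - tau) * a$foot_mass,
                 tolerance = 1e-12)
    expect_equal(a$masses[["midfoot"]], a$masses[["forefoot"]])
  }

  expect_error(build_anthropometrics(70, list(toes_volume_fraction = 0.7)),
               "toes_volume_fraction")
  expect_error(build_anthropometrics(-1), "body_mass")
})

test_that("inertial state is zero for a stationary pose", {
  traj <- compute_virtual_markers(static_traj(n = 30L))
  poses <- pose_time_series(traj, segment_definitions("right"))
  st <- segment_inertial_state(poses$hindfoot, 0.4, c(0.257, 0.245, 0.124))
  expect_lt(max(abs(st$vel)), 1e-9)
  expect_lt(max(abs(st$acc)), 1e-6)
  expect_lt(max(abs(st$omega)), 1e-9)
  expect_lt(max(abs(st$alpha_ang)), 1e-6)
  expect_true(all(st$inertia > 0))
})

test_that("free-fall translation and constant spin are recovered from poses", {
  n <- 60L; rate <- 60; g <- 9.80665
  tt <- (0:(n - 1)) / rate
  origin <- cbind(0, -0.5 * g * 1000 * tt^2, 0)   # mm
  R <- array(diag(3), c(3, 3, n))
  pose <- structure(list(name = "seg", R = R, origin = origin,
                         length = rep(100, n), gap = rep(FALSE, n), rate = rate),
                    class = "segment_pose")
  st <- segment_inertial_state(pose, 1, c(0.25, 0.25, 0.12))
  interior <- 5:(n - 5)
  expect_lt(max(abs(st$acc[interior, 2] + g)) / g, 0.01)

  spin <- pose
  for (t in seq_len(n)) spin$R[, , t] <- rot_y(2 * (t - 1) / rate * 180 / pi)
  spin$origin <- matrix(0, n, 3)
  st2 <- segment_inertial_state(spin, 1, c(0.25, 0.25, 0.12))
  w_mag <- sqrt(rowSums(st2$omega[interior, ]^2))
  expect_lt(max(abs(w_mag - 2)), 1e-3)
  expect_lt(max(abs(st2$alpha_ang[interior, ])), 1e-2)
})

test_that("a static massless foot under an anterior CoP gives the closed-form ankle moment", {
  traj <- compute_virtual_markers(static_traj(n = 30L))
  poses <- pose_time_series(traj, segment_definitions("right"))
  anthro <- build_anthropometrics(64, list(foot_mass_fraction = 1e-15))
  ajc <- traj$positions$V_AnkleJC[1, ]
  cop <- matrix(rep(c(ajc[1] + 100, 0, ajc[3]), each = 30), 30, 3)
  fp <- force_plate_record(matrix(rep(c(0, 600, 0), each = 30), 30, 3),
                           cop, numeric(30), rate = 60)
  kset <- inverse_dynamics(poses, anthro, fp, side = "right")
  M <- kset$joints$ankle$moment_lab[15, ]
  expect_equal(sqrt(sum(M^2)), 60, tolerance = 1e-9)
  # pure moment about the medio-lateral (z) axis
  expect_lt(max(abs(M[1:2])), 1e-9)
})

test_that("with zero GRF the static joint moment equals the gravitational moment", {
  traj <- compute_virtual_markers(static_traj(n = 30L))
  poses <- pose_time_series(traj, segment_definitions("right"))
  anthro <- build_anthropometrics(64)
  fp <- force_plate_record(matrix(0, 30, 3), matrix(NA_real_, 30, 3),
                           numeric(30), rate = 60)
  kset <- inverse_dynamics(poses, anthro, fp, side = "right")
  g <- c(0, -9.80665, 0)
  for (jn in c("ankle", "chopart", "lisfranc", "mtp1")) {
    segs <- switch(jn, ankle = c("hindfoot", "midfoot", "forefoot", "hallux"),
                   chopart = c("midfoot", "forefoot", "hallux"),
                   lisfranc = c("forefoot", "hallux"), mtp1 = "hallux")
    cJ <- switch(jn, ankle = , chopart = poses$midfoot$origin[1, ],
                 lisfranc = poses$forefoot$origin[1, ],
                 mtp1 = poses$hallux$origin[1, ]) / 1000
    expected <- c(0, 0, 0)
    for (sg in segs) {
      com <- (poses[[sg]]$origin[1, ] +
                poses[[sg]]$R[, 3, 1] * poses[[sg]]$length[1] / 2) / 1000
      expected <- expected + cross3_test(com - cJ, -anthro$masses[[sg]] * g)
    }
    expect_equal(unname(kset$joints[[jn]]$moment_lab[15, ]), unname(expected),
                 tolerance = 1e-9)
  }
})

test_that("vectorized inverse dynamics matches the brute-force free-body oracle", {
  # a handful of varied synthetic trials here; the full 20-trial sweep runs
  # in the acceptance suite
  cases <- list(c(seed = 21, noise = 0), c(seed = 22, noise = 1),
                c(seed = 23, noise = 2))
  for (cs in cases) {
    tr <- generate_trial(synthetic_trial_spec(seed = cs[["seed"]],
                                              marker_noise_sd = cs[["noise"]]))
    poses <- pose_time_series(compute_virtual_markers(tr$traj),
                              segment_definitions("right"))
    fp60 <- resample_force_to_markers(tr$fp, 60)
    anthro <- build_anthropometrics(64)
    kset <- inverse_dynamics(poses, anthro, fp60, side = "right")
    ref <- newton_euler_reference(poses, anthro, fp60)
    for (jn in names(ref)) {
      expect_lt(max(abs(kset$joints[[jn]]$moment_lab - ref[[jn]]$moment)), 1e-6)
      expect_lt(max(abs(kset$joints[[jn]]$force_lab - ref[[jn]]$force)), 1e-6)
      expect_lt(max(abs(kset$joints[[jn]]$power - ref[[jn]]$power)), 1e-6)
    }
  }
})

test_that("doubling the GRF doubles exactly the external moment component", {
  tr <- cached_trial(seed = 1)
  poses <- pose_time_series(compute_virtual_markers(tr$traj),
                            segment_definitions("right"))
  fp1 <- resample_force_to_markers(tr$fp, 60)
  # zero the sub-threshold tails so doubling does not create new loaded
  # frames lacking a CoP
  fp1$force[!fp1$cop_valid, ] <- 0
  fp1$tz[!fp1$cop_valid] <- 0
  fp0 <- fp1; fp0$force[] <- 0; fp0$tz[] <- 0
  fp0$cop_valid[] <- FALSE; fp0$cop[] <- NA_real_
  fp2 <- fp1; fp2$force <- 2 * fp1$force; fp2$tz <- 2 * fp1$tz
  anthro <- build_anthropometrics(64)
  k0 <- inverse_dynamics(poses, anthro, fp0, side = "right")
  k1 <- inverse_dynamics(poses, anthro, fp1, side = "right")
  k2 <- inverse_dynamics(poses, anthro, fp2, side = "right")
  for (jn in names(k1$joints)) {
    ext1 <- k1$joints[[jn]]$moment_lab - k0$joints[[jn]]$moment_lab
    ext2 <- k2$joints[[jn]]$moment_lab - k0$joints[[jn]]$moment_lab
    expect_lt(max(abs(ext2 - 2 * ext1)), 1e-9)
  }
})

test_that("joint power is a mass-normalized dot product with relative angular velocity", {
  expect_equal(joint_power(c(1, 0, 0), c(2, 0, 0), c(0, 0, 0), 1), 2)
  expect_equal(joint_power(c(1, 2, 3), c(1, 1, 1), c(1, 1, 1), 70), 0)
  p <- joint_power(c(1, -2, 0.5), c(0.3, 1, 2), c(0.1, 0, 0), 70)
  pm <- joint_power(c(1, -2, 0.5), c(0.1, 0, 0), c(0.3, 1, 2), 70)
  expect_equal(p, -pm)
  expect_error(joint_power(matrix(1, 3, 3), matrix(1, 2, 3), matrix(1, 3, 3), 70),
               "aligned")
})

test_that("CPcross masks in anatomical order and never alters values", {
  tr <- cached_trial(seed = 1)
  kin <- cached_kinematics(seed = 1, cutoff = NULL)
  anthro <- build_anthropometrics(64)
  kset <- inverse_dynamics(kin$poses, anthro, kin$fp, events = kin$events,
                           side = "right")
  axis <- progression_axis(kin$traj, kin$events)
  masked <- cpcross_mask(kset, kin$fp, kin$poses, kin$events, axis)
  ci <- vapply(masked$joints, `[[`, numeric(1), "crossing_index")
  expect_true(all(diff(ci) >= 0))
  expect_true(all(ci >= 0 & ci <= 100))
  for (jn in names(kset$joints)) {
    expect_identical(masked$joints[[jn]]$moment, kset$joints[[jn]]$moment)
    expect_identical(masked$joints[[jn]]$power, kset$joints[[jn]]$power)
    expect_equal(masked$joints[[jn]]$masked, (0:100) < ci[[jn]])
  }
})

test_that("a CoP that never crosses a joint masks it fully with a warning", {
  tr <- cached_trial(seed = 1)
  kin <- cached_kinematics(seed = 1, cutoff = NULL)
  anthro <- build_anthropometrics(64)
  kset <- inverse_dynamics(kin$poses, anthro, kin$fp, events = kin$events,
                           side = "right")
  fp_back <- kin$fp
  fp_back$cop[, 1] <- fp_back$cop[, 1] - 1e6   # CoP far posterior
  w <- capture_warnings(
    masked <- cpcross_mask(kset, fp_back, kin$poses, kin$events, c(1, 0, 0)))
  expect_true(any(grepl("fully masked", w)))
  expect_true(all(masked$joints$mtp1$masked))
  expect_true(all(masked$joints$ankle$masked))
})

test_that("a constructed CoP ramp crosses a joint at the expected percent", {
  tr <- cached_trial(seed = 1)
  kin <- cached_kinematics(seed = 1, cutoff = NULL)
  anthro <- build_anthropometrics(64)
  kset <- inverse_dynamics(kin$poses, anthro, kin$fp, events = kin$events,
                           side = "right")
  # replace the CoP by a ramp that overtakes the (moving) MTP centre at 30%:
  # the anterior CoP-to-centre offset rises linearly from -200 mm, reaching
  # +0.001 mm exactly at the 30% grid point
  ev <- kin$events
  grid <- ev$heel_strike + (0:100) / 100 * (ev$cycle_end - ev$heel_strike)
  c_mtp <- kin$poses$hallux$origin
  nt <- nrow(c_mtp)
  fp_ramp <- kin$fp
  frac <- (seq_len(nt) - ev$heel_strike) / (grid[31] - ev$heel_strike)
  fp_ramp$cop <- cbind(c_mtp[, 1] + 200 * (frac - 1) + 0.001 * frac, 0, c_mtp[, 3])
  fp_ramp$cop_valid <- rep(TRUE, nt)
  masked <- cpcross_mask(kset, fp_ramp, kin$poses, ev, c(1, 0, 0))
  expect_equal(masked$joints$mtp1$crossing_index, 30)
})
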