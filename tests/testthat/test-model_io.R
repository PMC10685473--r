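test_that("long CSV marker files read back exactly what was written", {
  pos <- list(A = cbind(1:5, 6:10, 11:15),
              B = cbind(rnorm(5), rnorm(5), rnorm(5)),
              C = matrix(0, 5, 3))
  traj <- marker_trajectories(pos, rate = 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_markers_csv(traj, path)
  back <- load_marker_trajectories(path, trial_config())
  expect_setequal(back$labels, c("A", "B", "C"))
  expect_equal(n_frames(back), 5L)
  for (lb in back$labels) {
    expect_lt(max(abs(back$positions[[lb]] - traj$positions[[lb]])), 1e-6)
  }
})

test_that("TRC files declared in metres are coerced to millimetres", {
  traj <- marker_trajectories(list(M = cbind(1:12, 2:13, 3:14)), rate = 60)
  path <- withr::local_tempfile(fileext = ".trc")
  write_trc(traj, path, units = "m")
  back <- load_marker_trajectories(path, trial_config())
  expect_equal(back$positions$M, traj$positions$M, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("synthetic trial survives write/read round trips losslessly", {
  tr <- cached_trial(seed = 2)
  td <- withr::local_tempdir()
  write_markers_csv(tr$traj, file.path(td, "m.csv"))
  write_trc(tr$traj, file.path(td, "m.trc"))
  write_force_csv(tr$fp, file.path(td, "f.csv"))
  for (f in c("m.csv", "m.trc")) {
    back <- load_marker_trajectories(file.path(td, f), trial_config())
    err <- max(vapply(back$labels, function(lb)
      max(abs(back$positions[[lb]] - tr$traj$positions[[lb]])), numeric(1L)))
    expect_lt(err, 1e-6)
  }
  fp2 <- load_force_plate(file.path(td, "f.csv"), trial_config())
  expect_lt(max(abs(fp2$force - tr$fp$force)), 1e-9)
  expect_equal(fp2$cop_valid, tr$fp$cop_valid)
})

test_that("loader errors name unsupported formats and missing markers", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines("nonsense", path)
  expect_error(load_marker_trajectories(path, trial_config()), "unsupported format")

  traj <- static_traj(n = 5L)
  traj$positions$NV <- NULL
  traj$gaps$NV <- NULL
  traj$labels <- names(traj$positions)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_markers_csv(traj, path2)
  expect_error(load_marker_trajectories(path2, trial_config(), check_required = TRUE),
               "NV")
})

test_that("marker label mapping and axis permutation are applied", {
  pos <- list(PT1 = matrix(rep(c(10, 20, 30), each = 4), 4, 3))
  traj <- marker_trajectories(pos, rate = 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_markers_csv(traj, path)
  cfg <- trial_config(marker_map = c(PT1 = "BC"),
                      marker_axis_map = c("+x", "+z", "-y"))
  back <- load_marker_trajectories(path, cfg)
  expect_equal(back$labels, "BC")
  expect_equal(unname(back$positions$BC[1, ]), c(10, 30, -20))
})

test_that("CoP is computed from raw plate moments by the plate equations", {
  # F = (0, 0, -600) N in a z-up plate frame; M_x = -60 N m -> CoP_y = +100 mm
  df <- data.frame(time = (0:9) / 1200, fx = 0, fy = 0, fz = -600,
                   mx = -60000, my = 0, mz = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  fp <- load_force_plate(path, trial_config(force_axis_map = c("+x", "+z", "+y")))
  expect_equal(unname(fp$force[1, ]), c(0, -600, 0))
  # plate y maps to internal z
  expect_equal(unname(fp$cop[1, ]), c(0, 0, 100))
  expect_true(all(fp$cop_valid))
})

test_that("pre-computed CoP columns pass through unchanged", {
  df <- data.frame(time = (0:9) / 1200, fx = 1, fy = 500, fz = 2,
                   copx = 11, copy = 22, copz = 33, tz = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  fp <- load_force_plate(path, trial_config())
  expect_equal(unname(fp$cop[3, ]), c(11, 22, 33))
  expect_equal(fp$tz, rep(4, 10))
})

test_that("an all-zero vertical force yields an empty-contact warning", {
  df <- data.frame(time = (0:9) / 1200, fx = 0, fy = 0, fz = 0,
                   copx = 0, copy = 0, copz = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_warning(fp <- load_force_plate(path, trial_config()), "empty contact|never reaches")
  expect_s3_class(fp, "force_plate_record")
})

test_that("force resampling preserves constants, sinusoids, counts and integrals", {
  n <- 1200L
  const <- force_plate_record(matrix(rep(c(0, -600, 0), each = n), n, 3L),
                              matrix(0, n, 3L), rate = 1200)
  out <- resample_force_to_markers(const, 60)
  expect_equal(nrow(out$force), 60L)
  expect_lt(max(abs(out$force[, 2L] + 600)), 1e-6)

  tt <- (0:(n - 1L)) / 1200
  sine <- 300 * sin(2 * pi * 2 * tt)
  fp <- force_plate_record(cbind(0, sine, 0), matrix(0, n, 3L), rate = 1200)
  out2 <- resample_force_to_markers(fp, 60)
  t60 <- (seq_len(nrow(out2$force)) - 1L) / 60
  mid <- 10:50
  expect_lt(max(abs(out2$force[mid, 2L] - 300 * sin(2 * pi * 2 * t60[mid]))), 3)
  # time-integral of a band-limited bump is preserved within 1%
  bump <- ifelse(tt >= 0.2 & tt <= 0.7, 600 * sin(pi * (tt - 0.2) / 0.5)^2, 0)
  fpb <- force_plate_record(cbind(0, bump, 0), matrix(0, n, 3L), rate = 1200)
  outb <- resample_force_to_markers(fpb, 60)
  int_in <- sum(bump) / 1200
  int_out <- sum(outb$force[, 2L]) / 60
  expect_lt(abs(int_out - int_in) / int_in, 0.01)

  expect_error(resample_force_to_markers(out2, 1200), "upsampling refused")
})

test_that("short marker gaps are interpolated and long gaps are fatal", {
  pos <- matrix(as.numeric(1:60), 20, 3)
  pos[8:10, ] <- NA
  traj <- marker_trajectories(list(BC = pos), rate = 60)
  filled <- interpolate_gaps(traj, max_gap = 5L)
  expect_false(any(filled$gaps$BC))
  expect_equal(unname(filled$positions$BC[9, 1]), 9)

  tr <- cached_trial(seed = 1)
  traj2 <- tr$traj
  traj2$positions$NV[10:25, ] <- NA
  traj2$gaps$NV[10:25] <- TRUE
  cfg <- trial_config(body_mass = 64)
  expect_error(joint_angle_pipeline(traj2, tr$fp, cfg), "NV")
})

test_that("trial configs read from YAML and reject unknown fields", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("side: left", "body_mass: 71.5", "filter_cutoff: 8"), path)
  cfg <- read_trial_config(path)
  expect_equal(cfg$side, "left")
  expect_equal(cfg$body_mass, 71.5)
  expect_equal(cfg$filter_cutoff, 8)
  writeLines("bogus_field: 1", path)
  expect_error(read_trial_config(path), "bogus_field")
})
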