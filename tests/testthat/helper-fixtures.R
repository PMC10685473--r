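# Shared fixtures: cached synthetic trials and small construction helpers.

.fixture_cache <- new.env(parent = emptyenv())

cached_trial <- function(seed = 1L, noise = 0, side = "right") {
  key <- paste0("trial_", seed, "_", noise, "_", side)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_trial(
      synthetic_trial_spec(seed = seed, marker_noise_sd = noise, side = side))
  }
  .fixture_cache[[key]]
}

cached_kinematics <- function(seed = 1L, noise = 0, side = "right",
                              cutoff = NULL) {
  key <- paste0("kin_", seed, "_", noise, "_", side, "_",
                if (is.null(cutoff)) "none" else cutoff)
  if (is.null(.fixture_cache[[key]])) {
    tr <- cached_trial(seed, noise, side)
    cfg <- trial_config(side = side, body_mass = 64, filter_cutoff = cutoff)
    .fixture_cache[[key]] <- joint_angle_pipeline(tr$traj, tr$fp, cfg)
  }
  .fixture_cache[[key]]
}

cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Uniform random rotation matrix (via normalized quaternion).
random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L)
}

# Static-pose trial: the neutral geometry replicated over `n` frames.
static_traj <- function(n = 120L, side = "right") {
  g <- neutral_geometry(side)
  marker_trajectories(lapply(g, function(v) {
    matrix(rep(v, each = n), n, 3L)
  }), rate = 60)
}

static_events <- function() {
  structure(list(heel_strike = 1L, toe_off = 61L, cycle_end = 101L,
                 stance_fraction = 0.6, extrapolated = FALSE),
            class = "gait_events")
}

# Constant-force plate record at 60 Hz with CoP fixed under the foot.
static_force <- function(n = 120L, fy = 600, cop = c(40, 0, 0)) {
  force_plate_record(
    force = matrix(rep(c(0, fy, 0), each = n), n, 3L),
    cop = matrix(rep(cop, each = n), n, 3L),
    tz = numeric(n), rate = 60)
}
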