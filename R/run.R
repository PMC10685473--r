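#' Run the full pipeline on one trial and write results
#'
#' Loads marker and force-plate files, runs the kinematic pipeline
#' (angles + MLA), and, when a body mass is configured, the kinetic pipeline
#' twice: unmasked and with CPcross masking. Writes tidy CSV outputs, an
#' events JSON and a run manifest into `out_dir`.
#'
#' Output files: `angles.csv` (joint, plane, percent, angle_deg),
#' `mla.csv`, `moments.csv` and `powers.csv` (with `masked` flags and
#' crossing indices; values are identical between masked and unmasked
#' reporting, masking only flags visibility), `events.json`,
#' `manifest.json`.
#'
#' @param markers_path marker file (TRC or long CSV)
#' @param force_path force-plate CSV
#' @param config a [trial_config()] or path to a YAML config
#' @param out_dir output directory (created if needed)
#' @param convention moment sign convention, `"plantar"` (plantarflexion
#'   positive, the usual convention for foot joint moments; default) or
#'   `"dorsi"` (sagittal sign matching the angle convention)
#' @return the run manifest, invisibly
#' @export
run_trial <- function(markers_path, force_path, config = trial_config(),
                      out_dir = ".", convention = "plantar") {
  if (is.character(config)) config <- read_trial_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "footmodel", version = as.character(utils::packageVersion("footmodel")),
    command = "run", inputs = list(markers = markers_path, force = force_path),
    side = config$side, convention = convention,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = character(), outputs = character(), warnings = character()
  )
  finish <- function(m) {
    m$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    m
  }
  result <- tryCatch({
    traj <- load_marker_trajectories(markers_path, config, check_required = TRUE)
    fp <- load_force_plate(force_path, config)
    manifest$stages <- c(manifest$stages, "load")
    kin <- joint_angle_pipeline(traj, fp, config)
    manifest$stages <- c(manifest$stages, "kinematics")

    ang <- do.call(rbind, lapply(names(kin$angles), function(jn) {
      a <- kin$angles[[jn]]
      data.frame(joint = jn,
                 plane = rep(c("sagittal", "frontal", "transverse"), each = 101L),
                 percent = rep(0:100, 3L),
                 angle_deg = c(a[, "alpha_x"], a[, "beta_z"], a[, "gamma_y"]))
    }))
    utils::write.csv(ang, file.path(out_dir, "angles.csv"), row.names = FALSE)
    mla <- data.frame(percent = 0:100, length_mm = kin$mla$length,
                      height_mm = kin$mla$height, ratio = kin$mla$ratio)
    utils::write.csv(mla, file.path(out_dir, "mla.csv"), row.names = FALSE)
    manifest$outputs <- c(manifest$outputs, "angles.csv", "mla.csv")

    ev <- kin$events
    ev_json <- list(heel_strike = ev$heel_strike, toe_off = ev$toe_off,
                    cycle_end = ev$cycle_end, stance_fraction = ev$stance_fraction,
                    extrapolated = ev$extrapolated)

    if (!is.na(config$body_mass)) {
      anthro <- build_anthropometrics(config$body_mass, config$anthro)
      kset <- inverse_dynamics(kin$poses, anthro, kin$fp, events = ev,
                               side = config$side, convention = convention)
      axis <- progression_axis(kin$traj, ev)
      kset <- withCallingHandlers(
        cpcross_mask(kset, kin$fp, kin$poses, ev, axis),
        warning = function(w) {
          manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      manifest$stages <- c(manifest$stages, "kinetics", "cpcross")

      mom <- do.call(rbind, lapply(names(kset$joints), function(jn) {
        j <- kset$joints[[jn]]
        data.frame(joint = jn,
                   plane = rep(c("sagittal", "frontal", "transverse"), each = 101L),
                   percent = rep(0:100, 3L),
                   moment_nm_kg = c(j$moment[, 1L], j$moment[, 2L], j$moment[, 3L]),
                   masked = rep(j$masked, 3L))
      }))
      utils::write.csv(mom, file.path(out_dir, "moments.csv"), row.names = FALSE)
      pow <- do.call(rbind, lapply(names(kset$joints), function(jn) {
        j <- kset$joints[[jn]]
        data.frame(joint = jn, percent = 0:100, power_w_kg = j$power,
                   masked = j$masked)
      }))
      utils::write.csv(pow, file.path(out_dir, "powers.csv"), row.names = FALSE)
      manifest$outputs <- c(manifest$outputs, "moments.csv", "powers.csv")
      ev_json$cpcross_crossing_percent <- lapply(kset$joints, `[[`, "crossing_index")
    }
    jsonlite::write_json(ev_json, file.path(out_dir, "events.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest$outputs <- c(manifest$outputs, "events.json", "manifest.json")
    manifest$status <- "ok"
    finish(manifest)
  }, error = function(e) {
    manifest$status <- "error"
    manifest$error <- conditionMessage(e)
    finish(manifest)
    stop(e)
  })
  invisible(result)
}

#' Generate a synthetic trial and write it to disk
#'
#' Writes the marker trajectories (long CSV and TRC), the force-plate CSV,
#' a ground-truth JSON (waveform curves on the 101-point cycle grid, event
#' frames, neutral angles, stance fraction) and a manifest. Deterministic
#' for a fixed spec and seed.
#'
#' @param spec a [synthetic_trial_spec()], or path to a YAML file with any
#'   of the scalar fields (`stance_fraction`, `cadence`, `walking_speed`,
#'   `body_mass`, `marker_noise_sd`, `seed`, `side`)
#' @param out_dir output directory
#' @param seed optional seed override
#' @return the manifest, invisibly
#' @export
simulate_trial <- function(spec = healthy_default_spec(), out_dir = ".",
                           seed = NULL) {
  if (is.character(spec)) {
    raw <- yaml::read_yaml(spec)
    allowed <- c("stance_fraction", "cadence", "walking_speed", "body_mass",
                 "marker_noise_sd", "seed", "side")
    unknown <- setdiff(names(raw), allowed)
    if (length(unknown)) {
      stop("simulate_trial: unknown spec field(s): ", paste(unknown, collapse = ", "))
    }
    spec <- do.call(synthetic_trial_spec, raw)
  }
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trial <- generate_trial(spec)
  write_markers_csv(trial$traj, file.path(out_dir, "markers.csv"))
  write_trc(trial$traj, file.path(out_dir, "markers.trc"))
  write_force_csv(trial$fp, file.path(out_dir, "force.csv"))
  tr <- trial$truth
  truth_json <- list(
    angles = lapply(tr$angles, function(a) as.data.frame(a)),
    neutral = tr$neutral,
    events = list(heel_strike = tr$events$heel_strike,
                  toe_off = tr$events$toe_off,
                  cycle_end = tr$events$cycle_end),
    cycle_frames = tr$cycle_frames,
    stance_fraction = tr$stance_fraction
  )
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    tool = "footmodel", version = as.character(utils::packageVersion("footmodel")),
    command = "simulate", seed = spec$seed, side = spec$side,
    stance_fraction = spec$stance_fraction,
    marker_noise_sd = spec$marker_noise_sd,
    outputs = c("markers.csv", "markers.trc", "force.csv", "truth.json",
                "manifest.json"),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), status = "ok"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Compute a CMC reliability report from tidy curve files
#'
#' Reads one or more tidy CSV files with columns
#' `measure, subject, trial, percent, value`, assembles the per-measure,
#' per-subject trial ensembles, and writes the [reliability_report()] table.
#' Ensembles with fewer than two trials are skipped with a warning.
#'
#' @param paths character vector of CSV paths (a glob is expanded with
#'   [Sys.glob()])
#' @param out_path output CSV path
#' @return the report data.frame, invisibly
#' @export
reliability_run <- function(paths, out_path = "reliability.csv") {
  files <- unique(unlist(lapply(paths, function(p) {
    if (file.exists(p)) p else Sys.glob(p)
  })))
  if (!length(files)) stop("reliability_run: no input files found")
  df <- do.call(rbind, lapply(files, utils::read.csv))
  need <- c("measure", "subject", "trial", "percent", "value")
  if (!all(need %in% names(df))) {
    stop("reliability_run: expected columns ", paste(need, collapse = ", "))
  }
  ensembles <- list()
  for (ms in unique(df$measure)) {
    dms <- df[df$measure == ms, ]
    subj_list <- list()
    for (sb in unique(dms$subject)) {
      dsb <- dms[dms$subject == sb, ]
      trials <- unique(dsb$trial)
      if (length(trials) < 2L) {
        warning("reliability_run: skipping singleton ensemble (measure ", ms,
                ", subject ", sb, ")")
        next
      }
      curves <- t(vapply(trials, function(tr) {
        d1 <- dsb[dsb$trial == tr, ]
        d1$value[order(d1$percent)]
      }, numeric(sum(dsb$trial == trials[1L]))))
      subj_list[[as.character(sb)]] <- curves
    }
    if (length(subj_list)) ensembles[[as.character(ms)]] <- subj_list
  }
  if (!length(ensembles)) stop("reliability_run: no valid ensembles (need >= 2 trials)")
  report <- reliability_report(ensembles)
  utils::write.csv(report, out_path, row.names = FALSE)
  invisible(report)
}
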