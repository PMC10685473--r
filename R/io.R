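#' Trial configuration
#'
#' Bundles the per-trial settings used by the loaders and the pipeline:
#' label mapping, side, body mass, filter settings and axis conventions.
#' Marker files from different vendors disagree on which axis is vertical;
#' `marker_axis_map` / `force_axis_map` give, for each internal axis
#' (x anterior, y up, z left), the signed file axis it comes from, e.g.
#' `c("+x", "+z", "+y")` for a z-up file.
#'
#' @param marker_map named character vector mapping file labels to canonical
#'   labels (`c(fileLabel = "canonical")`); NULL keeps labels as-is
#' @param side `"right"` or `"left"`
#' @param body_mass body mass in kg (required for kinetics)
#' @param filter_cutoff marker low-pass cut-off in Hz (default 6); NULL
#'   disables filtering
#' @param grf_cutoff optional low-pass cut-off for the force record; default
#'   NULL (off)
#' @param contact_threshold vertical-force contact threshold in N
#' @param stance_fraction assumed stance fraction for cycle-end extrapolation
#' @param units marker units of CSV files (`"mm"` or `"m"`); TRC files
#'   declare their own units
#' @param marker_axis_map,force_axis_map axis maps as described above
#' @param plate_origin plate origin offset (file frame, mm) used when CoP is
#'   computed from raw moment channels
#' @param anthro named list of anthropometric overrides passed to
#'   [build_anthropometrics()]
#' @return an object of class `trial_config`
#' @export
trial_config <- function(marker_map = NULL,
                         side = c("right", "left"),
                         body_mass = NA_real_,
                         filter_cutoff = 6,
                         grf_cutoff = NULL,
                         contact_threshold = 20,
                         stance_fraction = 0.60,
                         units = c("mm", "m"),
                         marker_axis_map = c("+x", "+y", "+z"),
                         force_axis_map = c("+x", "+y", "+z"),
                         plate_origin = c(0, 0, 0),
                         anthro = list()) {
  side <- match.arg(side)
  units <- match.arg(units)
  if (!is.na(body_mass) && body_mass <= 0) stop("trial_config: body_mass must be > 0")
  if (!is.null(filter_cutoff) && filter_cutoff <= 0) stop("trial_config: filter_cutoff must be > 0")
  structure(
    list(marker_map = marker_map, side = side, body_mass = body_mass,
         filter_cutoff = filter_cutoff, grf_cutoff = grf_cutoff,
         contact_threshold = contact_threshold,
         stance_fraction = stance_fraction, units = units,
         marker_axis_map = marker_axis_map, force_axis_map = force_axis_map,
         plate_origin = plate_origin, anthro = anthro),
    class = "trial_config"
  )
}

#' Read a trial configuration from YAML
#'
#' Any field of [trial_config()] may appear in the YAML file; missing fields
#' take their defaults.
#'
#' @param path YAML file path
#' @return a `trial_config`
#' @export
read_trial_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(trial_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("read_trial_config: unknown field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$marker_map)) raw$marker_map <- unlist(raw$marker_map)
  do.call(trial_config, raw)
}

# Apply a signed axis permutation ("+x","-z",...) to a T x 3 matrix.
apply_axis_map <- function(mat, map) {
  stopifnot(length(map) == 3L)
  idx <- match(sub("^[-+]", "", map), c("x", "y", "z"))
  if (anyNA(idx) || anyDuplicated(idx)) stop("invalid axis map: ", paste(map, collapse = ","))
  sgn <- ifelse(substr(map, 1L, 1L) == "-", -1, 1)
  out <- sweep(mat[, idx, drop = FALSE], 2L, sgn, `*`)
  colnames(out) <- c("x", "y", "z")
  out
}

rename_markers <- function(labels, marker_map) {
  if (is.null(marker_map)) return(labels)
  hit <- match(labels, names(marker_map))
  labels[!is.na(hit)] <- unname(marker_map[hit[!is.na(hit)]])
  labels
}

check_required_markers <- function(labels, registry) {
  req <- c(registry$physical, registry$shank)
  missing <- setdiff(req, labels)
  if (length(missing)) {
    stop("missing required marker(s) after label mapping: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Load marker trajectories from TRC or long-format CSV
#'
#' Supported dialects: TRC (tab-separated, units taken from the file header)
#' and long-format CSV with columns `time, marker, x, y, z` (units from the
#' config, default mm). File labels are renamed through the config's
#' `marker_map`, coordinates are permuted into the internal frame through
#' `marker_axis_map` and coerced to millimetres. When `check_required` is
#' TRUE the canonical eleven-marker foot set plus shank references must all
#' be present after mapping.
#'
#' @param path file path (`.trc` or `.csv`)
#' @param config a [trial_config()]
#' @param check_required verify the canonical marker set is complete
#' @return a `marker_trajectories` object (mm, internal frame)
#' @export
load_marker_trajectories <- function(path, config = trial_config(),
                                     check_required = FALSE) {
  if (!file.exists(path)) stop("load_marker_trajectories: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
    trc = read_trc(path),
    csv = read_markers_csv(path, units = config$units),
    stop("load_marker_trajectories: unsupported format '.", ext,
         "' (supported: .trc, .csv)")
  )
  names(parsed$positions) <- rename_markers(names(parsed$positions), config$marker_map)
  parsed$positions <- lapply(parsed$positions, apply_axis_map, map = config$marker_axis_map)
  traj <- marker_trajectories(parsed$positions, parsed$rate)
  if (check_required) check_required_markers(traj$labels, marker_set_registry(config$side))
  traj
}

read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L || !grepl("^PathFileType", lines[1L])) {
    stop("read_trc: not a TRC file: ", path)
  }
  keys <- strsplit(lines[2L], "\t")[[1L]]
  vals <- strsplit(lines[3L], "\t")[[1L]]
  meta <- stats::setNames(as.list(vals), keys)
  rate <- as.numeric(meta[["DataRate"]])
  units <- meta[["Units"]]
  header <- strsplit(lines[4L], "\t")[[1L]]
  labels <- header[-(1:2)]
  labels <- labels[labels != ""]
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(body, "\t")
  mat <- t(vapply(fields, function(f) as.numeric(f[seq_len(2L + 3L * length(labels))]),
                  numeric(2L + 3L * length(labels))))
  scale <- switch(units, mm = 1, m = 1000, cm = 10,
                  stop("read_trc: unsupported units '", units, "'"))
  positions <- lapply(seq_along(labels), function(i) {
    scale * mat[, (3L + 3L * (i - 1L)):(5L + 3L * (i - 1L)), drop = FALSE]
  })
  names(positions) <- labels
  list(positions = positions, rate = rate)
}

#' Write marker trajectories to a TRC file
#'
#' @param traj a `marker_trajectories` object
#' @param path output path
#' @param units `"mm"` (default) or `"m"`
#' @return `path`, invisibly
#' @export
write_trc <- function(traj, path, units = c("mm", "m")) {
  units <- match.arg(units)
  scale <- if (units == "m") 1 / 1000 else 1
  nt <- n_frames(traj)
  nm <- length(traj$labels)
  hdr <- c(
    paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t"),
    paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
            "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames"), collapse = "\t"),
    paste(c(traj$rate, traj$rate, nt, nm, units, traj$rate, 1, nt), collapse = "\t"),
    paste(c("Frame#", "Time", vapply(traj$labels, function(lb) paste0(lb, "\t\t"), "")),
          collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), nm), rep(seq_len(nm), each = 3L))),
          collapse = "\t")
  )
  block <- do.call(cbind, lapply(traj$positions, function(p) p * scale))
  rows <- cbind(seq_len(nt), (seq_len(nt) - 1L) / traj$rate, block)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

read_markers_csv <- function(path, units = "mm") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "marker", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("read_markers_csv: expected columns time, marker, x, y, z")
  }
  times <- sort(unique(df$time))
  if (length(times) < 2L) stop("read_markers_csv: need at least 2 frames")
  rate <- 1 / stats::median(diff(times))
  scale <- if (units == "m") 1000 else 1
  labels <- unique(df$marker)
  positions <- lapply(labels, function(lb) {
    sub <- df[df$marker == lb, ]
    sub <- sub[match(times, sub$time), ]
    cbind(x = sub$x, y = sub$y, z = sub$z) * scale
  })
  names(positions) <- labels
  list(positions = positions, rate = rate)
}

#' Write marker trajectories to long-format CSV
#'
#' Columns `time, marker, x, y, z`, coordinates in mm, one row per marker and
#' frame. This is the package's reference fixture dialect.
#'
#' @param traj a `marker_trajectories` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_markers_csv <- function(traj, path) {
  tt <- frame_times(traj)
  rows <- do.call(rbind, lapply(traj$labels, function(lb) {
    p <- traj$positions[[lb]]
    data.frame(time = tt, marker = lb, x = p[, 1L], y = p[, 2L], z = p[, 3L])
  }))
  utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Force-plate record container
#'
#' @param force T x 3 force matrix (N, internal frame)
#' @param cop T x 3 centre-of-pressure matrix (mm, internal frame); NA where
#'   undefined
#' @param tz free vertical moment series (N mm); zeros when absent
#' @param rate sampling rate (Hz)
#' @param contact_threshold vertical-force magnitude (N) below which the CoP
#'   is treated as undefined
#' @return an object of class `force_plate_record` with a `cop_valid`
#'   logical element
#' @export
force_plate_record <- function(force, cop, tz = NULL, rate,
                               contact_threshold = 20) {
  force <- as.matrix(force); cop <- as.matrix(cop)
  stopifnot(ncol(force) == 3L, ncol(cop) == 3L, nrow(force) == nrow(cop))
  if (is.null(tz)) tz <- numeric(nrow(force))
  stopifnot(length(tz) == nrow(force), rate > 0)
  valid <- abs(force[, 2L]) >= contact_threshold & apply(is.finite(cop), 1L, all)
  cop[!valid, ] <- NA_real_
  colnames(force) <- colnames(cop) <- c("x", "y", "z")
  structure(
    list(force = force, cop = cop, tz = as.numeric(tz), rate = as.numeric(rate),
         cop_valid = valid, contact_threshold = contact_threshold),
    class = "force_plate_record"
  )
}

#' @export
print.force_plate_record <- function(x, ...) {
  cat("<force_plate_record> ", nrow(x$force), " samples @ ", x$rate, " Hz, ",
      sum(x$cop_valid), " in contact (|Fy| >= ", x$contact_threshold, " N)\n",
      sep = "")
  invisible(x)
}

#' Load a force-plate record from CSV
#'
#' Two layouts are accepted. With pre-computed CoP the columns are
#' `time, fx, fy, fz, copx, copy, copz` and optionally `tz`; the CoP passes
#' through unchanged (then permuted by the config's `force_axis_map`). With
#' raw plate channels the columns are `time, fx, fy, fz, mx, my, mz`
#' (moments in N mm about the plate origin) and the CoP is computed by the
#' standard plate equations in the file's plate frame (z vertical):
#' `cop_x = -my/fz + ox`, `cop_y = mx/fz + oy`, `cop_z = oz` on the plate
#' surface, with the free vertical moment
#' `tz = mz - (cop_x - ox) * fy + (cop_y - oy) * fx`. For raw channels the
#' config's `force_axis_map` should map the z-up plate frame into the
#' internal y-up frame (e.g. `c("+x", "+z", "+y")`).
#'
#' @param path CSV path
#' @param config a [trial_config()]
#' @return a `force_plate_record` (N, mm, internal frame)
#' @export
load_force_plate <- function(path, config = trial_config()) {
  if (!file.exists(path)) stop("load_force_plate: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need_f <- c("time", "fx", "fy", "fz")
  if (!all(need_f %in% names(df))) {
    stop("load_force_plate: expected columns time, fx, fy, fz")
  }
  rate <- 1 / stats::median(diff(df$time))
  force_file <- cbind(df$fx, df$fy, df$fz)
  if (all(c("copx", "copy", "copz") %in% names(df))) {
    cop_file <- cbind(df$copx, df$copy, df$copz)
    tz_file <- if ("tz" %in% names(df)) df$tz else numeric(nrow(df))
  } else if (all(c("mx", "my", "mz") %in% names(df))) {
    o <- config$plate_origin
    fz <- df$fz
    small <- abs(fz) < config$contact_threshold
    copx <- -df$my / fz + o[1L]
    copy_ <- df$mx / fz + o[2L]
    copx[small] <- NA_real_; copy_[small] <- NA_real_
    cop_file <- cbind(copx, copy_, o[3L])
    tz_file <- df$mz - (copx - o[1L]) * df$fy + (copy_ - o[2L]) * df$fx
    tz_file[small] <- 0
  } else {
    stop("load_force_plate: need either copx/copy/copz or mx/my/mz columns")
  }
  force <- apply_axis_map(force_file, config$force_axis_map)
  cop <- apply_axis_map(cop_file, config$force_axis_map)
  if (max(abs(force[, 2L]), na.rm = TRUE) < config$contact_threshold) {
    warning("load_force_plate: vertical force never reaches the contact threshold (empty contact)")
  }
  force_plate_record(force, cop, tz_file, rate,
                     contact_threshold = config$contact_threshold)
}

#' Write a force-plate record to CSV
#'
#' Writes the pre-computed-CoP layout read back by [load_force_plate()].
#'
#' @param fp a `force_plate_record`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_force_csv <- function(fp, path) {
  tt <- (seq_len(nrow(fp$force)) - 1L) / fp$rate
  df <- data.frame(time = tt,
                   fx = fp$force[, 1L], fy = fp$force[, 2L], fz = fp$force[, 3L],
                   copx = fp$cop[, 1L], copy = fp$cop[, 2L], copz = fp$cop[, 3L],
                   tz = fp$tz)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a force-plate record to the marker rate
#'
#' Force channels are low-pass filtered (zero-phase Butterworth at 40% of
#' the target Nyquist) before decimation to prevent aliasing, then sampled
#' at the marker frame times by linear interpolation. The CoP is resampled
#' only inside contact intervals (no filtering -- the CoP is a quotient and
#' is undefined off the plate); contact validity is re-derived from the
#' resampled vertical force.
#'
#' @param fp a `force_plate_record`
#' @param marker_rate target rate in Hz; must not exceed `fp$rate`
#' @return a `force_plate_record` at `marker_rate`
#' @export
resample_force_to_markers <- function(fp, marker_rate) {
  if (marker_rate > fp$rate) {
    stop("resample_force_to_markers: upsampling refused (marker rate ",
         marker_rate, " > plate rate ", fp$rate, ")")
  }
  if (marker_rate == fp$rate) return(fp)
  nt <- nrow(fp$force)
  t_in <- (seq_len(nt) - 1L) / fp$rate
  t_out <- seq(0, t_in[nt], by = 1 / marker_rate)
  cutoff <- 0.8 * marker_rate / 2
  ff <- butterworth_lowpass(fp$force, cutoff, fp$rate)
  force_out <- apply(ff, 2L, function(col) stats::approx(t_in, col, xout = t_out)$y)
  tz_out <- stats::approx(t_in, butterworth_lowpass(fp$tz, cutoff, fp$rate),
                          xout = t_out)$y
  cop_out <- matrix(NA_real_, length(t_out), 3L)
  valid_in <- which(fp$cop_valid)
  if (length(valid_in) >= 2L) {
    tv <- t_in[valid_in]
    # contact at the output rate: the anti-alias filter spreads force onset
    # by a fraction of a frame, so the CoP is pinned to the nearest contact
    # sample at the interval boundaries
    contact_out <- abs(force_out[, 2L]) >= fp$contact_threshold
    for (j in 1:3) {
      cop_out[contact_out, j] <- stats::approx(tv, fp$cop[valid_in, j],
                                               xout = t_out[contact_out],
                                               rule = 2L)$y
    }
  }
  force_plate_record(force_out, cop_out, tz_out, marker_rate,
                     contact_threshold = fp$contact_threshold)
}
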