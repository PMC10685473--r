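#' Default anthropometric constants
#'
#' The whole-foot mass fraction of body mass and the per-axis radii of
#' gyration (as fractions of segment long-axis length) follow the standard
#' adjusted cadaver-based tables used in gait analysis; the toe (hallux)
#' volume fraction of the whole foot follows classical segment-volume data.
#' All values are editable parameters, not measurements: override any of
#' them through the `params` argument of [build_anthropometrics()] or the
#' `anthro` field of [trial_config()].
#'
#' @format list with `foot_mass_fraction` (0.0137), `toes_volume_fraction`
#'   (0.08) and `radii` (fractions of segment length about the x, y, z
#'   segment axes: 0.257, 0.245, 0.124)
#' @export
anthro_defaults <- list(
  foot_mass_fraction = 0.0137,
  toes_volume_fraction = 0.08,
  radii = c(x = 0.257, y = 0.245, z = 0.124)
)

#' Build the anthropometric model for the four foot segments
#'
#' The whole-foot mass is a fixed fraction of body mass. Segment masses are
#' apportioned by assumed segment volumes under homogeneous density: with
#' `tau` the toe fraction of whole-foot volume, the hindfoot takes half of
#' the remaining (non-toe) foot, and the midfoot and forefoot take a quarter
#' each; the hallux takes `tau`. Segment centres of mass sit halfway along
#' the segment long axis and the inertia tensor is diagonal in the segment
#' frame, `I_k = m * (r_k * L)^2`, with per-axis radii of gyration `r_k`
#' expressed as fractions of segment length.
#'
#' @param body_mass body mass in kg
#' @param params named list of overrides: `foot_mass_fraction`,
#'   `toes_volume_fraction` (`tau`, in (0, 0.5)), `radii` (length-3)
#' @return object of class `anthropometric_model` with elements `body_mass`,
#'   `foot_mass`, `masses` (hindfoot, midfoot, forefoot, hallux; kg), `tau`,
#'   `radii` (4 x 3 matrix of fractions), `com_rule`
#' @export
build_anthropometrics <- function(body_mass, params = list()) {
  if (!is.numeric(body_mass) || body_mass <= 0) {
    stop("build_anthropometrics: body_mass must be > 0")
  }
  p <- utils::modifyList(anthro_defaults, params)
  tau <- p$toes_volume_fraction
  if (!(tau > 0 && tau < 0.5) && tau != 0) {
    stop("build_anthropometrics: toes_volume_fraction must lie in (0, 0.5)")
  }
  r <- unlist(p$radii)
  if (length(r) != 3L || any(r <= 0) || any(r >= 1)) {
    stop("build_anthropometrics: radii must be three fractions in (0, 1)")
  }
  foot_mass <- p$foot_mass_fraction * body_mass
  masses <- c(
    hindfoot = 0.5 * (1 - tau) * foot_mass,
    midfoot  = 0.25 * (1 - tau) * foot_mass,
    forefoot = 0.25 * (1 - tau) * foot_mass,
    hallux   = tau * foot_mass
  )
  radii <- matrix(rep(r, each = 4L), 4L, 3L,
                  dimnames = list(names(masses), c("x", "y", "z")))
  structure(
    list(body_mass = body_mass, foot_mass = foot_mass, masses = masses,
         tau = tau, foot_mass_fraction = p$foot_mass_fraction, radii = radii,
         com_rule = "midpoint of segment long axis"),
    class = "anthropometric_model"
  )
}

#' @export
print.anthropometric_model <- function(x, ...) {
  cat("<anthropometric_model> body mass ", x$body_mass, " kg, foot mass ",
      signif(x$foot_mass, 4), " kg (fraction ", x$foot_mass_fraction, ")\n",
      sep = "")
  m <- signif(x$masses, 4)
  cat("  segment masses (kg):", paste(names(m), m, sep = "=", collapse = ", "),
      "\n  toe volume fraction:", x$tau, "\n")
  invisible(x)
}
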