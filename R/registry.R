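#' Marker-set registry for the four-segment foot model
#'
#' The model places eleven physical markers on each foot: lateral and medial
#' malleoli (LM, MM), top and bottom calcaneus (TC, BC), talar head (TH),
#' navicular (NV), cuboid (CB), first and fifth metatarsal heads (MTH1,
#' MTH5), a marker between the second and third metatarsal heads (MTH23) and
#' the hallux nail bed (HLX). Two shank reference markers (KNL, KNM, lateral
#' and medial knee) provide the proximal segment for the ankle. Virtual
#' markers are midpoints of physical pairs:
#' \describe{
#'   \item{V_AnkleJC}{midpoint of MM and LM (ankle joint centre)}
#'   \item{V_MidNC}{midpoint of NV and CB}
#'   \item{V_15MTH}{midpoint of MTH1 and MTH5}
#'   \item{V_KneeJC}{midpoint of KNL and KNM}
#' }
#'
#' @param side `"right"` or `"left"`
#' @return an object of class `marker_set_registry` with elements `physical`
#'   (the 11 foot markers), `shank`, `virtual` (named list of defining pairs)
#'   and `side`
#' @export
marker_set_registry <- function(side = c("right", "left")) {
  side <- match.arg(side)
  structure(
    list(
      physical = c("LM", "MM", "TC", "BC", "TH", "NV", "CB",
                   "MTH1", "MTH5", "MTH23", "HLX"),
      shank = c("KNL", "KNM"),
      virtual = list(
        V_AnkleJC = c("MM", "LM"),
        V_MidNC   = c("NV", "CB"),
        V_15MTH   = c("MTH1", "MTH5"),
        V_KneeJC  = c("KNL", "KNM")
      ),
      side = side
    ),
    class = "marker_set_registry"
  )
}

#' @export
print.marker_set_registry <- function(x, ...) {
  cat("<marker_set_registry> side:", x$side, "\n")
  cat("  physical foot markers (", length(x$physical), "): ",
      paste(x$physical, collapse = ", "), "\n", sep = "")
  cat("  shank reference:", paste(x$shank, collapse = ", "), "\n")
  cat("  virtual:", paste(names(x$virtual), collapse = ", "), "\n")
  invisible(x)
}

#' Append virtual markers to a trajectory set
#'
#' Each virtual marker is the midpoint of its two defining markers,
#' frame by frame. A frame gapped in either defining marker is gapped in the
#' virtual marker.
#'
#' @param traj a `marker_trajectories` object containing the physical markers
#' @param registry a `marker_set_registry`
#' @return `traj` with the virtual marker labels appended
#' @export
compute_virtual_markers <- function(traj, registry = marker_set_registry()) {
  for (vm in names(registry$virtual)) {
    pair <- registry$virtual[[vm]]
    missing <- setdiff(pair, traj$labels)
    if (length(missing)) {
      stop("compute_virtual_markers: missing defining marker(s) ",
           paste(missing, collapse = ", "), " for ", vm)
    }
    a <- traj$positions[[pair[1L]]]
    b <- traj$positions[[pair[2L]]]
    traj$positions[[vm]] <- (a + b) / 2
    traj$gaps[[vm]] <- traj$gaps[[pair[1L]]] | traj$gaps[[pair[2L]]]
    traj$labels <- names(traj$positions)
  }
  traj
}

#' Segment definitions for the four-segment foot model
#'
#' Each body segment is defined by three markers: the Origin marker (the
#' segment's proximal end), the Long Axis marker (distal end; the segment
#' z-axis runs origin to long-axis marker and the distance between them is
#' the segment length) and the Plane marker (completes the y-z plane; the
#' x-axis is the right-handed normal of that plane). Fixed RX/RY/RZ offsets
#' (degrees, applied as intrinsic rotations about the constructed axes in the
#' order x, y, z) align every segment's axes with the anatomical convention:
#' z anterior, y up, x lateral. The table ships as a YAML file under
#' `extdata` and can be overridden with a user file of the same layout.
#'
#' @param side `"right"` or `"left"`
#' @param file optional path to a YAML override with the same structure as
#'   the packaged `segment_definitions.yaml`
#' @return a named list of `segment_definition` lists (fields `name`,
#'   `parent`, `origin`, `long_axis`, `plane`, `rx`, `ry`, `rz`) in
#'   parent-first topological order: shank, hindfoot, midfoot, forefoot,
#'   hallux
#' @export
segment_definitions <- function(side = c("right", "left"), file = NULL) {
  side <- match.arg(side)
  if (is.null(file)) {
    file <- system.file("extdata", "segment_definitions.yaml",
                        package = "footmodel", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(file)
  if (is.null(raw[[side]])) stop("segment_definitions: no '", side, "' entry in ", file)
  defs <- lapply(raw[[side]], function(d) {
    d <- d[c("name", "parent", "origin", "long_axis", "plane", "rx", "ry", "rz")]
    stopifnot(!anyNA(match(c("name", "origin", "long_axis", "plane"), names(d))))
    for (f in c("rx", "ry", "rz")) if (is.null(d[[f]])) d[[f]] <- 0
    if (is.null(d$parent)) d$parent <- "Global"
    if (length(unique(c(d$origin, d$long_axis, d$plane))) != 3L) {
      stop("segment_definitions: origin, long-axis and plane markers must be distinct for ", d$name)
    }
    structure(d, class = "segment_definition")
  })
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}

#' Joints of the four-segment chain
#'
#' Returns the joint table linking each articulation to its proximal and
#' distal segments and to the marker whose position is taken as the joint
#' centre (the distal segment's origin marker).
#'
#' @return data.frame with columns `joint`, `parent`, `child`, `centre`
#' @export
foot_joints <- function() {
  data.frame(
    joint  = c("ankle", "chopart", "lisfranc", "mtp1"),
    parent = c("shank", "hindfoot", "midfoot", "forefoot"),
    child  = c("hindfoot", "midfoot", "forefoot", "hallux"),
    centre = c("V_AnkleJC", "V_AnkleJC", "V_MidNC", "MTH1"),
    stringsAsFactors = FALSE
  )
}
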