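#' Medial longitudinal arch height/length ratio
#'
#' The arch length is the distance between the first metatarsal head (MTH1)
#' and the bottom calcaneus (BC) markers; the arch height is the magnitude of
#' the perpendicular from the navicular (NV) marker to the MTH1-BC line. The
#' ratio height/length is dimensionless and invariant to rigid motion and
#' uniform scaling of the foot; in healthy gait it falls through stance as
#' the arch compresses, reaching its minimum shortly before toe off.
#'
#' @param bc,mth1,nv T x 3 matrices (or length-3 vectors) of marker
#'   positions (mm)
#' @return object of class `mla_series`: data.frame with columns `length`,
#'   `height` (mm) and `ratio`
#' @export
mla_ratio <- function(bc, mth1, nv) {
  bc <- rbind(bc, deparse.level = 0)
  mth1 <- rbind(mth1, deparse.level = 0)
  nv <- rbind(nv, deparse.level = 0)
  stopifnot(ncol(bc) == 3L, nrow(bc) == nrow(mth1), nrow(bc) == nrow(nv))
  axis <- mth1 - bc
  len <- sqrt(rowSums(axis^2))
  if (any(len == 0, na.rm = TRUE)) {
    stop("mla_ratio: BC and MTH1 coincide; arch length undefined")
  }
  w <- nv - bc
  proj <- rowSums(w * axis) / len
  height <- sqrt(pmax(rowSums(w^2) - proj^2, 0))
  structure(
    data.frame(length = len, height = height, ratio = height / len),
    class = c("mla_series", "data.frame")
  )
}
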