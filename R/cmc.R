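#' Coefficient of multiple correlation for waveform repeatability
#'
#' Computes the within-day coefficient of multiple correlation (Kadaba's
#' formulation) over an ensemble of repeated-trial curves of one outcome
#' measure. With `Y[j, t]` the j-th of M trials at time point t (of T),
#' `Ybar_t` the time-point mean and `Ybar` the grand mean:
#' \deqn{R = \sqrt{1 - \frac{\sum_{j,t} (Y_{jt} - \bar Y_t)^2 / (T(M-1))}
#'                      {\sum_{j,t} (Y_{jt} - \bar Y)^2 / (MT-1)}}}
#' R approaches 1 when trials repeat the same waveform and falls toward 0
#' as between-trial scatter approaches the waveform's own excursion. The
#' result is flagged undefined (rather than clamped) when the denominator is
#' zero -- identical flat curves carry no waveform information -- or when the
#' radicand is negative.
#'
#' @param curves M x T numeric matrix, one row per trial (M >= 2, T >= 2),
#'   gap-free
#' @return object of class `cmc_result`: list with `R` and `defined`
#' @export
cmc <- function(curves) {
  curves <- as.matrix(curves)
  M <- nrow(curves); Tn <- ncol(curves)
  if (M < 2L || Tn < 2L) stop("cmc: need at least 2 trials and 2 time points")
  if (anyNA(curves)) stop("cmc: curves must be gap-free")
  ybar_t <- colMeans(curves)
  ybar <- mean(curves)
  within <- sum(sweep(curves, 2L, ybar_t)^2) / (Tn * (M - 1L))
  total <- sum((curves - ybar)^2) / (M * Tn - 1L)
  if (total <= 0) {
    return(structure(list(R = NA_real_, defined = FALSE), class = "cmc_result"))
  }
  radicand <- 1 - within / total
  if (radicand < 0) {
    return(structure(list(R = NA_real_, defined = FALSE), class = "cmc_result"))
  }
  structure(list(R = sqrt(radicand), defined = TRUE), class = "cmc_result")
}

#' @export
print.cmc_result <- function(x, ...) {
  if (x$defined) cat("CMC R =", round(x$R, 3), "(", classify_reliability(x$R), ")\n")
  else cat("CMC undefined (degenerate ensemble)\n")
  invisible(x)
}

#' Classify a CMC coefficient
#'
#' `R >= 0.7` is labelled `"strong"`, `0.3 <= R < 0.7` `"moderate"`,
#' `R < 0.3` `"poor"`. The boundary value 0.7 is assigned to `"strong"`.
#' Undefined coefficients (see [cmc()]) are labelled `"undefined"`.
#'
#' @param R a numeric coefficient or a `cmc_result`
#' @return character label
#' @export
classify_reliability <- function(R) {
  if (inherits(R, "cmc_result")) {
    if (!R$defined) return("undefined")
    R <- R$R
  }
  if (is.na(R)) return("undefined")
  if (R >= 0.7) "strong" else if (R >= 0.3) "moderate" else "poor"
}

#' Reliability report across subjects and outcome measures
#'
#' Computes one CMC per subject and outcome measure and summarizes across
#' subjects: the mean coefficient, its standard deviation across subjects
#' (NA for a single subject) and the reliability label of the mean.
#'
#' @param ensembles nested list: `ensembles[[measure]][[subject]]` is an
#'   M x T matrix of repeated-trial curves
#' @return data.frame with columns `measure`, `n_subjects`, `R`, `SD`,
#'   `label`
#' @export
reliability_report <- function(ensembles) {
  stopifnot(length(ensembles) >= 1L)
  rows <- lapply(names(ensembles), function(ms) {
    rs <- vapply(ensembles[[ms]], function(cv) cmc(cv)$R, numeric(1L))
    rs_def <- rs[!is.na(rs)]
    mean_r <- if (length(rs_def)) mean(rs_def) else NA_real_
    data.frame(measure = ms,
               n_subjects = length(rs),
               R = mean_r,
               SD = if (length(rs_def) > 1L) stats::sd(rs_def) else NA_real_,
               label = classify_reliability(mean_r),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
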