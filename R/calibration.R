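#' Raw generalized polarization of an intensity pair
#'
#' The uncalibrated (G = 1) GP of ordered/disordered channel intensities,
#' \eqn{(I_o - I_d) / (I_o + I_d)}. Applied to a calibration standard this is
#' the measured reference GP (GPmes) that, together with the literature value
#' GPref, determines the instrument calibration factor.
#'
#' Inputs are vectorized; each pair must have positive total intensity.
#'
#' @param ordered,disordered non-negative intensities (numeric vectors).
#' @return numeric vector of GP values in (-1, 1).
#' @examples
#' rawGP(3, 1)   # 0.5
#' rawGP(1, 3)   # -0.5
#' @export
rawGP <- function(ordered, disordered) {
  tot <- ordered + disordered
  if (any(!is.finite(tot)) || any(tot <= 0))
    stop("raw GP undefined: ordered + disordered must be positive")
  (ordered - disordered) / tot
}

#' Calibration factor G from reference and measured GP
#'
#' Channel-sensitivity correction factor derived from a reference sample
#' (e.g. LUVs of defined lipid composition) of known GP:
#' \deqn{G = \frac{GP_{ref} + GP_{ref}GP_{mes} - GP_{mes} - 1}
#'            {GP_{mes} + GP_{ref}GP_{mes} - GP_{ref} - 1}}
#' algebraically equal to
#' \eqn{(1 - GP_{ref})(1 + GP_{mes}) / ((1 - GP_{mes})(1 + GP_{ref}))}.
#' Using this G in [gpMap()] maps any pair whose raw GP equals
#' \code{gpMes} back to \code{gpRef} exactly (the round-trip identity).
#'
#' @param gpRef reference GP of the calibration standard, in (-1, 1).
#' @param gpMes raw GP of the same standard measured with G = 1, in (-1, 1).
#' @return numeric, G > 0. \code{gpRef == gpMes} gives exactly 1.
#' @examples
#' calibrationG(0.6, 0.4)   # 0.5833...
#' calibrationG(0.2, 0.2)   # 1
#' @export
calibrationG <- function(gpRef, gpMes) {
  if (any(abs(gpRef) >= 1) || any(abs(gpMes) >= 1))
    stop("gpRef and gpMes must lie strictly inside (-1, 1)")
  (gpRef + gpRef * gpMes - gpMes - 1) / (gpMes + gpRef * gpMes - gpRef - 1)
}

#' Estimate a CalibrationReference from reference-vesicle intensities
#'
#' Computes the measured GP of a calibration standard as the mean raw GP over
#' per-vesicle (ordered, disordered) intensity pairs, then derives the
#' calibration factor against the supplied reference GP.
#'
#' @param pairs a data.frame (or matrix) with columns \code{ordered} and
#'   \code{disordered}, one row per vesicle/field.
#' @param gpRef known reference GP of the standard, in (-1, 1).
#' @return A [CalibrationReference-class].
#' @seealso [simCalibrationSet()] for a seeded synthetic standard.
#' @export
estimateCalibration <- function(pairs, gpRef) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("ordered", "disordered") %in% names(pairs)),
            nrow(pairs) >= 1L)
  gpMes <- mean(rawGP(pairs$ordered, pairs$disordered))
  if (abs(gpMes) >= 1)
    stop("measured reference GP out of (-1, 1)")
  new("CalibrationReference", gpRef = gpRef, gpMes = gpMes,
      gFactor = calibrationG(gpRef, gpMes))
}

#' @rdname estimateCalibration
#' @param x a \code{CalibrationReference}.
#' @export
gFactor <- function(x) {
  stopifnot(is(x, "CalibrationReference"))
  x@gFactor
}
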