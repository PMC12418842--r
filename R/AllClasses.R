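#' @import methods
NULL

#' Two registered fluorescence emission channels
#'
#' Container for a dual-channel ratiometric acquisition of an
#' environment-sensitive membrane dye (e.g. Di-4-ANEPPDHQ excited at 488 nm):
#' an "ordered" channel collecting 500--580 nm emission and a "disordered"
#' channel collecting 620--750 nm emission. Both grids are pixel-registered,
#' 0-based row-major by convention, in arbitrary detector units.
#'
#' @slot ordered numeric matrix, 500--580 nm channel intensities (>= 0).
#' @slot disordered numeric matrix, 620--750 nm channel intensities (>= 0),
#'   same dimensions as \code{ordered}.
#'
#' @seealso [ChannelPair()] for the constructor, [gpMap()] for the
#'   pixel-wise GP computation.
#' @export
setClass("ChannelPair",
  representation(ordered = "matrix", disordered = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@ordered) || !is.numeric(object@disordered))
      msg <- c(msg, "both channels must be numeric matrices")
    if (!identical(dim(object@ordered), dim(object@disordered)))
      msg <- c(msg, "channel dimensions differ")
    if (any(!is.finite(object@ordered)) || any(!is.finite(object@disordered)))
      msg <- c(msg, "channel intensities must be finite")
    else if (any(object@ordered < 0) || any(object@disordered < 0))
      msg <- c(msg, "channel intensities must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Instrument calibration derived from a reference sample
#'
#' Holds the reference GP of a calibration standard (typically large
#' unilamellar vesicles of defined lipid composition), the raw GP of the same
#' standard as measured on this instrument with G = 1, and the derived
#' channel-sensitivity correction factor G.
#'
#' @slot gpRef numeric(1), literature/reference GP of the standard, in (-1, 1).
#' @slot gpMes numeric(1), raw measured GP of the standard (G = 1), in (-1, 1).
#' @slot gFactor numeric(1), derived calibration factor, > 0.
#'
#' @seealso [calibrationG()], [estimateCalibration()]
#' @export
setClass("CalibrationReference",
  representation(gpRef = "numeric", gpMes = "numeric", gFactor = "numeric"),
  validity = function(object) {
    msg <- character()
    for (s in c("gpRef", "gpMes", "gFactor"))
      if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
        msg <- c(msg, sprintf("%s must be a finite scalar", s))
    if (!length(msg)) {
      if (abs(object@gpRef) >= 1 || abs(object@gpMes) >= 1)
        msg <- c(msg, "gpRef and gpMes must lie strictly inside (-1, 1)")
      if (object@gFactor <= 0)
        msg <- c(msg, "gFactor must be positive")
    }
    if (length(msg)) msg else TRUE
  })

#' Pixel-wise generalized-polarization map
#'
#' GP values per pixel together with a validity mask. Pixels whose combined
#' intensity falls at or below the intensity floor are marked invalid (never
#' clamped) and are excluded from all downstream statistics.
#'
#' @slot gp numeric matrix of GP values; finite and in [-1, 1] wherever valid.
#' @slot validMask logical matrix, TRUE where the GP value is usable.
#' @slot intensityFloor numeric(1), detector-unit floor used for masking.
#' @slot gFactorUsed numeric(1), calibration factor applied.
#'
#' @seealso [gpMap()], [summarizeROI()], [renderGPMap()]
#' @export
setClass("GPMap",
  representation(gp = "matrix", validMask = "matrix",
                 intensityFloor = "numeric", gFactorUsed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@gp), dim(object@validMask)))
      msg <- c(msg, "gp and validMask dimensions differ")
    if (!is.logical(object@validMask))
      msg <- c(msg, "validMask must be logical")
    else {
      v <- object@gp[object@validMask]
      if (any(!is.finite(v)) || any(abs(v) > 1))
        msg <- c(msg, "valid GP pixels must be finite and in [-1, 1]")
    }
    if (length(object@intensityFloor) != 1L || object@intensityFloor < 0)
      msg <- c(msg, "intensityFloor must be a non-negative scalar")
    if (length(object@gFactorUsed) != 1L || object@gFactorUsed <= 0)
      msg <- c(msg, "gFactorUsed must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' Membrane region of interest
#'
#' A boolean pixel mask delineating the plasma-membrane region of one cell,
#' either drawn manually (loaded from a mask file or polygon list) or produced
#' by the automatic ring segmentation.
#'
#' @slot mask logical matrix, TRUE on membrane pixels.
#' @slot cellId character(1) label.
#' @slot provenance character(1), \code{"manual"} or \code{"automatic"}.
#' @slot nPixels integer(1), number of TRUE pixels.
#'
#' @seealso [segmentMembranes()], [loadROIMasks()]
#' @export
setClass("MembraneROI",
  representation(mask = "matrix", cellId = "character",
                 provenance = "character", nPixels = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@mask))
      msg <- c(msg, "mask must be logical")
    else if (object@nPixels != sum(object@mask))
      msg <- c(msg, "nPixels does not match mask")
    if (!object@provenance %in% c("manual", "automatic"))
      msg <- c(msg, "provenance must be 'manual' or 'automatic'")
    if (length(msg)) msg else TRUE
  })

#' Two-group comparison result
#'
#' Full output of the shared comparison engine for one pair of groups:
#' difference of means (group b minus group a), its standard error, t
#' statistic, degrees of freedom (fractional under Welch), two-tailed p,
#' 95\% confidence interval, eta-squared/R-squared effect size
#' (t^2 / (t^2 + df)), and the variance-ratio F test.
#'
#' @slot groupA,groupB character(1) group labels.
#' @slot meanDiff,semDiff numeric(1), difference of means (b - a) and its SEM.
#' @slot tStat,df,pTwoTailed numeric(1), t statistic, degrees of freedom,
#'   two-tailed p value.
#' @slot ciLow,ciHigh numeric(1), 95\% confidence limits of the difference.
#' @slot rSquared numeric(1), effect size in [0, 1).
#' @slot fStat,fDf1,fDf2,fP numeric(1), variance-ratio F (>= 1), its
#'   numerator/denominator df, and two-tailed p.
#' @slot varianceModel character(1), \code{"pooled"} or \code{"welch"}.
#'
#' @seealso [compareGroups()]
#' @export
setClass("ComparisonResult",
  representation(groupA = "character", groupB = "character",
                 meanDiff = "numeric", semDiff = "numeric",
                 tStat = "numeric", df = "numeric", pTwoTailed = "numeric",
                 ciLow = "numeric", ciHigh = "numeric",
                 rSquared = "numeric",
                 fStat = "numeric", fDf1 = "numeric", fDf2 = "numeric",
                 fP = "numeric",
                 varianceModel = "character"),
  validity = function(object) {
    msg <- character()
    if (!(object@ciLow <= object@meanDiff && object@meanDiff <= object@ciHigh))
      msg <- c(msg, "CI must bracket the mean difference")
    if (object@rSquared < 0 || object@rSquared > 1)
      msg <- c(msg, "rSquared must lie in [0, 1]")
    if (is.finite(object@fStat) && object@fStat < 1)
      msg <- c(msg, "fStat is the larger/smaller variance ratio, >= 1")
    if (!object@varianceModel %in% c("pooled", "welch"))
      msg <- c(msg, "varianceModel must be 'pooled' or 'welch'")
    if (length(msg)) msg else TRUE
  })

#' @exportMethod show
setMethod("show", "ChannelPair", function(object) {
  d <- dim(object@ordered)
  cat(sprintf("ChannelPair: %d x %d px\n", d[1], d[2]))
  cat(sprintf("  ordered   (500-580 nm): range %.3g..%.3g\n",
              min(object@ordered), max(object@ordered)))
  cat(sprintf("  disordered(620-750 nm): range %.3g..%.3g\n",
              min(object@disordered), max(object@disordered)))
})

setMethod("show", "CalibrationReference", function(object) {
  cat(sprintf("CalibrationReference: GPref = %.4f, GPmes = %.4f, G = %.6f\n",
              object@gpRef, object@gpMes, object@gFactor))
})

setMethod("show", "GPMap", function(object) {
  d <- dim(object@gp)
  v <- object@gp[object@validMask]
  cat(sprintf("GPMap: %d x %d px, %d valid (%.1f%%), G = %.4f, floor = %g\n",
              d[1], d[2], length(v),
              100 * length(v) / prod(d), object@gFactorUsed,
              object@intensityFloor))
  if (length(v))
    cat(sprintf("  GP range %.3f..%.3f, mean %.3f\n",
                min(v), max(v), mean(v)))
})

setMethod("show", "MembraneROI", function(object) {
  cat(sprintf("MembraneROI '%s' (%s): %d px\n",
              object@cellId, object@provenance, object@nPixels))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("ComparisonResult: %s vs %s (%s)\n",
              object@groupA, object@groupB, object@varianceModel))
  cat(sprintf("  mean diff (b-a) = %.4g +/- %.4g (SEM), 95%% CI %.4g to %.4g\n",
              object@meanDiff, object@semDiff, object@ciLow, object@ciHigh))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g, R^2 = %.4g\n",
              object@tStat, object@df, object@pTwoTailed, object@rSquared))
  cat(sprintf("  F = %.4g (df %g, %g), p = %.4g\n",
              object@fStat, object@fDf1, object@fDf2, object@fP))
})
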