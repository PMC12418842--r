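#' Pixel-wise generalized-polarization map
#'
#' Computes per-pixel GP from a registered channel pair with calibration
#' factor G:
#' \deqn{GP = \frac{I_{500-580} - G\, I_{620-750}}
#'                 {I_{500-580} + G\, I_{620-750}}}
#' Pixels whose calibrated total intensity \eqn{I_o + G I_d} is at or below
#' \code{intensityFloor} are marked invalid, not clamped: masking keeps dim
#' background pixels out of ROI means instead of biasing them toward an
#' arbitrary value. With positive intensities and G > 0 every valid GP lies
#' strictly inside (-1, 1), and G = 1 recovers the uncalibrated estimator.
#'
#' @param channels a [ChannelPair-class].
#' @param gFactor calibration factor G > 0 (see [calibrationG()]), or a
#'   [CalibrationReference-class].
#' @param intensityFloor non-negative validity floor in detector units;
#'   default 0 (only strictly positive totals are valid).
#' @return A [GPMap-class].
#' @examples
#' cp <- ChannelPair(matrix(3, 1, 1), matrix(1, 1, 1))
#' gpValues(gpMap(cp, 1))   # 0.5
#' @export
gpMap <- function(channels, gFactor = 1, intensityFloor = 0) {
  stopifnot(is(channels, "ChannelPair"))
  if (is(gFactor, "CalibrationReference")) gFactor <- gFactor@gFactor
  stopifnot(length(gFactor) == 1L, is.finite(gFactor), gFactor > 0,
            length(intensityFloor) == 1L, intensityFloor >= 0)
  io <- channels@ordered
  id <- channels@disordered
  tot <- io + gFactor * id
  valid <- tot > intensityFloor
  gp <- matrix(NA_real_, nrow(io), ncol(io))
  gp[valid] <- (io[valid] - gFactor * id[valid]) / tot[valid]
  new("GPMap", gp = gp, validMask = valid,
      intensityFloor = as.numeric(intensityFloor),
      gFactorUsed = as.numeric(gFactor))
}

#' @rdname gpMap
#' @param x a \code{GPMap}.
#' @export
gpValues <- function(x) {
  stopifnot(is(x, "GPMap"))
  x@gp
}

#' @rdname gpMap
#' @export
validMask <- function(x) {
  stopifnot(is(x, "GPMap"))
  x@validMask
}

#' Per-cell GP summary over a membrane ROI
#'
#' Mean GP over the valid pixels of a membrane region, reported both on the
#' internal [-1, 1] scale and on the x100 reporting scale conventionally used
#' for group summaries (reported = 100 x internal, exactly). Invalid pixels
#' inside the ROI are excluded and do not count toward \code{nPixels}.
#'
#' @param gpMap a [GPMap-class].
#' @param roi a logical matrix the same shape as the map, or a
#'   [MembraneROI-class].
#' @param cellId,phenotype labels for the output row; phenotype is one of
#'   \code{"M0"}, \code{"M1"}, \code{"M2"} or \code{"unknown"}.
#' @return A one-row data.frame with columns \code{cell_id}, \code{phenotype},
#'   \code{n_pixels}, \code{mean_gp_internal}, \code{mean_gp_reported}.
#' @export
summarizeROI <- function(gpMap, roi, cellId = "cell1", phenotype = "unknown") {
  stopifnot(is(gpMap, "GPMap"))
  if (is(roi, "MembraneROI")) {
    if (identical(cellId, "cell1")) cellId <- roi@cellId
    roi <- roi@mask
  }
  stopifnot(is.logical(roi), identical(dim(roi), dim(gpMap@gp)))
  use <- roi & gpMap@validMask
  n <- sum(use)
  if (n == 0L)
    stop("empty ROI: no valid GP pixels under the mask for cell ", cellId)
  m <- mean(gpMap@gp[use])
  data.frame(cell_id = cellId, phenotype = phenotype, n_pixels = n,
             mean_gp_internal = m, mean_gp_reported = 100 * m,
             stringsAsFactors = FALSE)
}

#' Summarize many ROIs against one GP map
#'
#' @param gpMap a [GPMap-class].
#' @param rois list of [MembraneROI-class] objects.
#' @param phenotype phenotype label applied to every ROI (recycled).
#' @return data.frame, one row per ROI, as in [summarizeROI()].
#' @export
summarizeROIs <- function(gpMap, rois, phenotype = "unknown") {
  phenotype <- rep_len(phenotype, length(rois))
  do.call(rbind, lapply(seq_along(rois), function(i)
    summarizeROI(gpMap, rois[[i]], phenotype = phenotype[i])))
}

#' Render a GP map as an HSB-merged color image
#'
#' Pseudocolors membrane order and merges it with fluorescence intensity in
#' hue-saturation-brightness space: hue encodes GP linearly over
#' \code{gpRange} with blue at the high-GP (ordered) end and red at the
#' low-GP (disordered) end; saturation is 1; brightness is the mean of the
#' two channels normalized to [0, 1] by the \code{brightPercentile} quantile
#' (values above it are clipped). Invalid pixels are rendered black.
#'
#' @param gpMap a [GPMap-class].
#' @param channels the [ChannelPair-class] the map was computed from.
#' @param gpRange length-2 numeric, GP values mapped to the red and blue hue
#'   ends; must be strictly increasing. GP outside the range is clipped.
#' @param brightPercentile percentile (0-1] used to normalize brightness;
#'   default 0.99.
#' @return numeric array (rows x cols x 3) of RGB values in [0, 1].
#' @export
renderGPMap <- function(gpMap, channels, gpRange = c(-1, 1),
                        brightPercentile = 0.99) {
  stopifnot(is(gpMap, "GPMap"), is(channels, "ChannelPair"),
            identical(dim(gpMap@gp), dim(channels@ordered)),
            length(gpRange) == 2L)
  if (!(gpRange[2] > gpRange[1]))
    stop("degenerate GP range: gpRange must be strictly increasing")
  stopifnot(brightPercentile > 0, brightPercentile <= 1)

  inten <- (channels@ordered + channels@disordered) / 2
  ref <- stats::quantile(inten[gpMap@validMask], brightPercentile,
                         names = FALSE)
  if (!is.finite(ref) || ref <= 0) ref <- max(inten, 1e-12)
  bright <- pmin(inten / ref, 1)

  frac <- (gpMap@gp - gpRange[1]) / (gpRange[2] - gpRange[1])
  frac <- pmin(pmax(frac, 0), 1)
  hue <- frac * (2 / 3)               # 0 = red (disordered) .. 2/3 = blue (ordered)

  d <- dim(gpMap@gp)
  out <- array(0, c(d, 3L))
  ok <- which(gpMap@validMask)
  if (length(ok)) {
    cols <- grDevices::hsv(h = hue[ok], s = 1, v = bright[ok])
    rgb <- grDevices::col2rgb(cols) / 255
    n <- prod(d)
    out[ok] <- rgb[1L, ]
    out[ok + n] <- rgb[2L, ]
    out[ok + 2L * n] <- rgb[3L, ]
  }
  out
}

#' M1/M2 ratio of a per-cell measure
#'
#' Ratio of the M1 group mean to the M2 group mean of a chosen per-cell
#' measure (reported GP by default, or a channel-intensity column), used as a
#' simple phenotype-classification index.
#'
#' @param summaries data.frame with a \code{phenotype} column and the
#'   \code{measure} column (e.g. output of [summarizeROIs()]).
#' @param measure name of the numeric column to compare; default
#'   \code{"mean_gp_reported"}.
#' @return A list with \code{ratio}, \code{measure}, \code{mean_m1},
#'   \code{mean_m2}.
#' @examples
#' s <- data.frame(phenotype = c("M1", "M2"),
#'                 mean_gp_reported = c(63.56, 69.99))
#' m1m2Ratio(s)$ratio   # 0.9081...
#' @export
m1m2Ratio <- function(summaries, measure = "mean_gp_reported") {
  stopifnot(is.data.frame(summaries), measure %in% names(summaries),
            "phenotype" %in% names(summaries))
  m1 <- summaries[[measure]][summaries$phenotype == "M1"]
  m2 <- summaries[[measure]][summaries$phenotype == "M2"]
  if (!length(m1) || !length(m2))
    stop("need at least one M1 and one M2 cell")
  mu1 <- mean(m1); mu2 <- mean(m2)
  if (mu2 == 0) stop("undefined ratio: M2 mean is zero")
  list(ratio = mu1 / mu2, measure = measure, mean_m1 = mu1, mean_m2 = mu2)
}

#' Read / write GP maps as TIFF
#'
#' GP maps are stored as two-page 32-bit float TIFF: page 1 holds the GP
#' values affinely rescaled from [-1, 1] to [0, 1] (invalid pixels 0), page 2
#' the validity mask (0/1). The rescaling keeps the file inside the [0, 1]
#' storage range of the float TIFF writer and is inverted exactly on read.
#'
#' @param x a [GPMap-class].
#' @param path file path.
#' @return \code{readGPMap} returns a [GPMap-class]; the writer returns
#'   \code{path} invisibly.
#' @export
writeGPMap <- function(x, path) {
  stopifnot(is(x, "GPMap"))
  enc <- matrix(0, nrow(x@gp), ncol(x@gp))
  enc[x@validMask] <- (x@gp[x@validMask] + 1) / 2
  tiff::writeTIFF(list(enc, x@validMask * 1.0), path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname writeGPMap
#' @export
readGPMap <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L) stop("expected a two-page GP map TIFF at ", path)
  valid <- pages[[2L]] > 0.5
  gp <- matrix(NA_real_, nrow(valid), ncol(valid))
  gp[valid] <- pages[[1L]][valid] * 2 - 1
  new("GPMap", gp = gp, validMask = valid, intensityFloor = 0,
      gFactorUsed = 1)
}
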