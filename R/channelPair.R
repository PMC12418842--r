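#' Construct a ChannelPair
#'
#' @param ordered numeric matrix of 500--580 nm ("ordered") channel
#'   intensities, arbitrary detector units, all >= 0.
#' @param disordered numeric matrix of 620--750 nm ("disordered") channel
#'   intensities, same dimensions.
#' @return A [ChannelPair-class] object.
#' @examples
#' cp <- ChannelPair(matrix(3, 2, 2), matrix(1, 2, 2))
#' rawGP(orderedChannel(cp), disorderedChannel(cp))
#' @export
ChannelPair <- function(ordered, disordered) {
  new("ChannelPair", ordered = as.matrix(ordered),
      disordered = as.matrix(disordered))
}

#' @rdname ChannelPair
#' @param x a \code{ChannelPair}.
#' @export
orderedChannel <- function(x) {
  stopifnot(is(x, "ChannelPair"))
  x@ordered
}

#' @rdname ChannelPair
#' @export
disorderedChannel <- function(x) {
  stopifnot(is(x, "ChannelPair"))
  x@disordered
}

#' @describeIn ChannelPair pixel dimensions (rows, cols).
#' @export
setMethod("dim", "ChannelPair", function(x) dim(x@ordered))

#' Apply an integer-pixel registration shift to the disordered channel
#'
#' Simultaneous two-channel acquisition needs no registration, which is the
#' default elsewhere in the package; this helper corrects a known rigid
#' integer-pixel offset between the channels when one exists. Pixels shifted
#' in from outside the field are set to 0.
#'
#' @param x a [ChannelPair-class].
#' @param dr,dc integer row/column shift applied to the disordered channel.
#' @return A shifted \code{ChannelPair}.
#' @export
shiftChannels <- function(x, dr = 0L, dc = 0L) {
  stopifnot(is(x, "ChannelPair"))
  dr <- as.integer(dr); dc <- as.integer(dc)
  m <- x@disordered
  out <- matrix(0, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dr
  src_c <- seq_len(ncol(m)) - dc
  ok_r <- src_r >= 1L & src_r <= nrow(m)
  ok_c <- src_c >= 1L & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  ChannelPair(x@ordered, out)
}

#' Read / write dual-channel TIFF images
#'
#' Channel pairs are stored as two-page 16-bit grayscale TIFF (page 1 =
#' 500--580 nm channel, page 2 = 620--750 nm channel), with intensities as
#' integer detector counts (values are rounded on write; counts must not
#' exceed 65535). Alternatively two single-page files may be given.
#'
#' @param path path to a two-page TIFF, or (for the paired form) the ordered
#'   channel file.
#' @param disorderedPath optional path to a separate disordered-channel TIFF;
#'   when given, \code{path} is read as the ordered channel.
#' @return \code{readChannelPair} returns a [ChannelPair-class];
#'   \code{writeChannelPair} returns \code{path} invisibly.
#' @export
readChannelPair <- function(path, disorderedPath = NULL) {
  if (is.null(disorderedPath)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (length(pages) < 2L)
      stop("expected a two-page TIFF at ", path)
    ChannelPair(pages[[1L]] * 1.0, pages[[2L]] * 1.0)
  } else {
    ChannelPair(tiff::readTIFF(path, as.is = TRUE) * 1.0,
                tiff::readTIFF(disorderedPath, as.is = TRUE) * 1.0)
  }
}

#' @rdname readChannelPair
#' @param x a \code{ChannelPair} to write.
#' @export
writeChannelPair <- function(x, path) {
  stopifnot(is(x, "ChannelPair"))
  mx <- max(x@ordered, x@disordered)
  if (mx > 65535)
    stop("intensities exceed the 16-bit range of the TIFF container")
  tiff::writeTIFF(list(round(x@ordered) / 65535,
                       round(x@disordered) / 65535),
                  path, bits.per.sample = 16L)
  invisible(path)
}
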