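#' Automatic ring-shaped membrane segmentation
#'
#' Deterministic stand-in for manual freehand membrane selection: the summed
#' two-channel image is thresholded (Otsu's method, or a fixed threshold),
#' holes are filled, connected components are labeled, small components are
#' discarded, and each surviving component yields a ring mask — the filled
#' component minus its morphological erosion by the configured ring width —
#' approximating the plasma-membrane region. Components touching the image
#' border are discarded by default to avoid truncated rings.
#'
#' @param channels a [ChannelPair-class].
#' @param minRoiPx minimum pixel count for a component and its ring
#'   (default 50).
#' @param ringWidthPx erosion width in pixels defining the ring (default 3).
#' @param keepBorder keep components touching the image border
#'   (default FALSE).
#' @param threshold optional fixed threshold in detector units applied to
#'   the summed image instead of Otsu's method.
#' @return list of [MembraneROI-class] with provenance \code{"automatic"},
#'   ordered by component label; empty (with a warning) when nothing
#'   survives the filters.
#' @export
segmentMembranes <- function(channels, minRoiPx = 50L, ringWidthPx = 3L,
                             keepBorder = FALSE, threshold = NULL) {
  stopifnot(is(channels, "ChannelPair"), minRoiPx >= 1L, ringWidthPx >= 1L)
  total <- channels@ordered + channels@disordered
  mx <- max(total)
  if (mx <= 0) {
    warning("blank image: no membrane components found")
    return(list())
  }
  if (is.null(threshold)) {
    img <- EBImage::Image(total / mx)
    bw <- total / mx > EBImage::otsu(img)
  } else {
    bw <- total > threshold
  }
  filled <- EBImage::fillHull(EBImage::Image(bw * 1))
  lab <- EBImage::bwlabel(filled)
  labm <- EBImage::imageData(lab)
  nlab <- max(labm)
  if (nlab == 0) {
    warning("no membrane components found above threshold")
    return(list())
  }
  brush <- EBImage::makeBrush(2L * ringWidthPx + 1L, shape = "disc")
  h <- nrow(total); w <- ncol(total)
  rois <- list()
  for (k in seq_len(nlab)) {
    comp <- labm == k
    if (sum(comp) < minRoiPx) next
    if (!keepBorder &&
        (any(comp[1L, ]) || any(comp[h, ]) ||
         any(comp[, 1L]) || any(comp[, w]))) next
    eroded <- EBImage::imageData(
      EBImage::erode(EBImage::Image(comp * 1), brush)) > 0.5
    ring <- comp & !eroded
    if (sum(ring) < minRoiPx) next
    rois[[length(rois) + 1L]] <- new("MembraneROI", mask = ring,
      cellId = sprintf("auto_%03d", k), provenance = "automatic",
      nPixels = as.integer(sum(ring)))
  }
  if (!length(rois))
    warning("no membrane components survived the size/border filters")
  rois
}

#' Load membrane ROIs from a labeled mask
#'
#' Accepts an 8-bit labeled mask TIFF (or an integer/logical matrix): each
#' distinct positive label becomes one manual-provenance ROI.
#'
#' @param mask path to a single-page TIFF, or a matrix; nonzero values are
#'   ROI labels.
#' @param imageDim optional expected (rows, cols); a mismatch is an error.
#' @return list of [MembraneROI-class] with provenance \code{"manual"}.
#' @export
loadROIMasks <- function(mask, imageDim = NULL) {
  if (is.character(mask))
    mask <- round(tiff::readTIFF(mask, as.is = TRUE))
  mask <- as.matrix(mask)
  if (is.logical(mask)) mask <- mask * 1L
  if (!is.null(imageDim) && !identical(dim(mask), as.integer(imageDim)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match image shape ",
         paste(imageDim, collapse = "x"))
  labels <- sort(unique(mask[mask > 0]))
  lapply(labels, function(l)
    new("MembraneROI", mask = mask == l,
        cellId = sprintf("manual_%03d", as.integer(l)),
        provenance = "manual", nPixels = as.integer(sum(mask == l))))
}

# Even-odd point-in-polygon for pixel centers, boundary pixels included.
polygonMask <- function(rows, cols, vr, vc) {
  nv <- length(vr)
  mask <- matrix(FALSE, length(rows), length(cols))
  for (ri in seq_along(rows)) for (ci in seq_along(cols)) {
    y <- rows[ri]; x <- cols[ci]
    inside <- FALSE
    onEdge <- FALSE
    j <- nv
    for (i in seq_len(nv)) {
      yi <- vr[i]; xi <- vc[i]; yj <- vr[j]; xj <- vc[j]
      # boundary: collinear and within the segment bounding box
      cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
      if (abs(cross) < 1e-9 &&
          x >= min(xi, xj) - 1e-9 && x <= max(xi, xj) + 1e-9 &&
          y >= min(yi, yj) - 1e-9 && y <= max(yi, yj) + 1e-9) {
        onEdge <- TRUE
        break
      }
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi)
        inside <- !inside
      j <- i
    }
    mask[ri, ci] <- inside || onEdge
  }
  mask
}

#' Build membrane ROIs from polygon vertex lists
#'
#' Fills simple (non-self-intersecting) polygons on the 0-based pixel grid
#' using the even-odd rule; pixels whose centers lie on a polygon edge are
#' included.
#'
#' @param polygons data.frame with columns \code{cell_id},
#'   \code{vertex_index}, \code{row}, \code{col} (0-based pixel
#'   coordinates), or a path to such a comma-delimited file.
#' @param imageDim integer(2), (rows, cols) of the target image.
#' @return list of [MembraneROI-class] with provenance \code{"manual"}.
#' @examples
#' poly <- data.frame(cell_id = "c1", vertex_index = 1:4,
#'                    row = c(0, 0, 9, 9), col = c(0, 9, 9, 0))
#' roisFromPolygons(poly, c(10, 10))[[1]]@nPixels   # 100
#' @export
roisFromPolygons <- function(polygons, imageDim) {
  if (is.character(polygons))
    polygons <- utils::read.csv(polygons, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "vertex_index", "row", "col") %in%
                  names(polygons)))
  imageDim <- as.integer(imageDim)
  lapply(split(polygons, polygons$cell_id), function(p) {
    p <- p[order(p$vertex_index), ]
    if (nrow(p) < 3L)
      stop("malformed polygon '", p$cell_id[1L], "': needs >= 3 vertices")
    mask <- matrix(FALSE, imageDim[1L], imageDim[2L])
    rr <- max(0L, floor(min(p$row))):min(imageDim[1L] - 1L,
                                         ceiling(max(p$row)))
    cc <- max(0L, floor(min(p$col))):min(imageDim[2L] - 1L,
                                         ceiling(max(p$col)))
    mask[rr + 1L, cc + 1L] <- polygonMask(rr, cc, p$row, p$col)
    new("MembraneROI", mask = mask, cellId = as.character(p$cell_id[1L]),
        provenance = "manual", nPixels = as.integer(sum(mask)))
  })
}
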