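## Seed-based region growing and peripheral contour extraction.  The region
## at tolerance ST(x) is the connected component, through 8-adjacency and
## pairwise color similarity, containing the seed; its peripheral contour is
## the set of member pixels with at least one 8-neighbor (off-image positions
## included) outside the region.

.contourMask <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  # pad with FALSE so off-image neighbors count as outside
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  allin <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    allin <- allin & pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
  }
  mask & !allin
}

#' Grow a leaf region from a seed pixel
#'
#' Flood fill under the tolerance-of-similarity relation: a neighbor joins
#' the region when its color is within distance \code{x} of the member pixel
#' it is reached from (chained pairwise similarity, so tonality may drift
#' across the region).  The result equals the connected component of the
#' pixel graph whose edges join adjacent similar pixels, and therefore does
#' not depend on traversal order or on which member serves as seed.
#'
#' A region reaching all four image borders has escaped into the background
#' frame and is flagged flooded.
#'
#' @param image a \linkS4class{LeafImage}.
#' @param x tolerance upper bound, \code{1 <= x <= cmax - 1}.
#' @param seed length-2 (x = column, y = row), 1-based; defaults to the
#'   central pixel, the operator's "point inside the leaf".
#' @return a \linkS4class{LeafRegion}.
#' @examples
#' img <- LeafImage(array(10L, c(4, 4, 3)), unp = 1)
#' regionSize(growRegion(img, x = 1))  # 16: uniform image, all connected
#' @export
growRegion <- function(image, x, seed = NULL) {
  stopifnot(is(image, "LeafImage"))
  .checkTol(x, colorDepth(image))
  if (is.null(seed))
    seed <- c(ceiling(imageWidth(image) / 2), ceiling(imageHeight(image) / 2))
  seed <- as.integer(seed)
  .checkCoord(seed, image)
  mask <- cpp_grow_region(image@r, image@g, image@b,
                          seed[2] - 1L, seed[1] - 1L, as.numeric(x))
  flooded <- any(mask[1L, ]) && any(mask[nrow(mask), ]) &&
    any(mask[, 1L]) && any(mask[, ncol(mask)])
  new("LeafRegion", mask = mask, contour = .contourMask(mask), seed = seed,
      x = as.numeric(x), unp = imageScale(image), flooded = flooded)
}

#' Peripheral contour of a region
#'
#' The boundary pixels of a leaf region: members having at least one
#' 8-neighbor outside the region, where positions beyond the image border
#' count as outside.  Returned as an unordered coordinate set; measurements
#' never depend on a boundary ordering.
#'
#' @param region a nonempty \linkS4class{LeafRegion}.
#' @return integer matrix with columns x, y.
#' @export
peripheralContour <- function(region) {
  if (regionSize(region) == 0L) stop("empty region has no contour")
  contourCoords(region)
}

#' Ordered boundary walk (for visualization only)
#'
#' Orders the contour pixels by angle about the region centroid.  This is a
#' display aid; no measurement in the package consumes the ordering.
#'
#' @param region a \linkS4class{LeafRegion}.
#' @return integer matrix with columns x, y, ordered counter-clockwise.
#' @export
orderedContour <- function(region) {
  ct <- peripheralContour(region)
  cen <- colMeans(ct)
  ct[order(atan2(ct[, 2L] - cen[2L], ct[, 1L] - cen[1L])), , drop = FALSE]
}
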