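## Discrete color geometry: RGB distance, tolerance of similarity, pixel
## adjacency and connectivity.  Colors are points of the integer RGB cube
## [0, cmax - 1]^3; two pixels are similar at tolerance ST(x) = [0, x] when
## their Euclidean color distance is <= x, and connected when additionally
## 8-adjacent.

.checkColor <- function(p, cmax, what = "color") {
  if (length(p) != 3L || anyNA(p))
    stop(what, " must be a length-3 RGB vector", call. = FALSE)
  if (any(p < 0) || any(p > cmax - 1))
    stop(what, sprintf(" channels must lie in [0, %d]", cmax - 1L), call. = FALSE)
  invisible(p)
}

.checkTol <- function(x, cmax) {
  if (length(x) != 1L || is.na(x) || x < 1 || x > cmax - 1)
    stop(sprintf("tolerance x must satisfy 1 <= x <= %d", cmax - 1L),
         call. = FALSE)
  invisible(x)
}

.checkCoord <- function(p, image) {
  if (length(p) != 2L || anyNA(p))
    stop("pixel coordinate must be a length-2 (x, y) vector", call. = FALSE)
  if (p[1] < 1 || p[1] > imageWidth(image) || p[2] < 1 || p[2] > imageHeight(image))
    stop(sprintf("pixel (%g, %g) out of image bounds %d x %d",
                 p[1], p[2], imageWidth(image), imageHeight(image)),
         call. = FALSE)
  invisible(p)
}

#' Construct a LeafImage from an RGB array
#'
#' @param rgb a height x width x 3 numeric array of integer channel
#'   intensities in \code{[0, cmax - 1]}.
#' @param unp image scale, pixels per mm (> 0).
#' @param cmax color levels per channel; 256 for standard 8-bit RGB.
#' @return a \linkS4class{LeafImage}.
#' @examples
#' img <- LeafImage(array(0L, c(4, 6, 3)), unp = 1)
#' imageWidth(img)
#' @export
LeafImage <- function(rgb, unp, cmax = 256L) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("rgb must be a height x width x 3 array")
  storage.mode(rgb) <- "integer"
  d <- dim(rgb)
  ch <- function(i) matrix(rgb[, , i], d[1], d[2])
  new("LeafImage", r = ch(1L), g = ch(2L), b = ch(3L),
      unp = as.numeric(unp), cmax = as.integer(cmax))
}

#' Read a leaf image from a PNG (or TIFF) file
#'
#' Channel values are mapped to the integer scale \code{[0, cmax - 1]}; an
#' alpha channel, if present, is dropped and grayscale images are replicated
#' across the three channels.  Images whose bit depth differs from
#' \code{cmax} are rescaled on load (with a message).
#'
#' @param path file path; format chosen by extension (.png or .tif/.tiff,
#'   the latter requiring the tiff package).
#' @inheritParams LeafImage
#' @return a \linkS4class{LeafImage}.
#' @export
loadLeafImage <- function(path, unp, cmax = 256L) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  vals <- round(arr * 255)
  if (cmax != 256L) {
    message("rescaling 8-bit image to cmax = ", cmax)
    vals <- round(vals * (cmax - 1) / 255)
  }
  LeafImage(vals, unp = unp, cmax = cmax)
}

#' Write a LeafImage, a region mask, or a contour overlay as PNG
#'
#' @param image a \linkS4class{LeafImage}.
#' @param path output file path.
#' @param region optional \linkS4class{LeafRegion}; when given, `writeMaskPNG`
#'   writes its 1-bit membership mask and `writeOverlayPNG` the image with the
#'   peripheral contour burned in red, for quality control.
#' @return the path, invisibly.
#' @export
writeLeafImagePNG <- function(image, path) {
  arr <- array(0, c(imageHeight(image), imageWidth(image), 3L))
  sc <- 255 / (colorDepth(image) - 1L)
  arr[, , 1L] <- image@r * sc / 255
  arr[, , 2L] <- image@g * sc / 255
  arr[, , 3L] <- image@b * sc / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname writeLeafImagePNG
#' @export
writeMaskPNG <- function(region, path) {
  png::writePNG(region@mask * 1, path)
  invisible(path)
}

#' @rdname writeLeafImagePNG
#' @export
writeOverlayPNG <- function(image, region, path) {
  arr <- array(0, c(imageHeight(image), imageWidth(image), 3L))
  sc <- 1 / (colorDepth(image) - 1L)
  arr[, , 1L] <- image@r * sc
  arr[, , 2L] <- image@g * sc
  arr[, , 3L] <- image@b * sc
  ct <- region@contour
  arr[, , 1L][ct] <- 1
  arr[, , 2L][ct] <- 0
  arr[, , 3L][ct] <- 0
  png::writePNG(arr, path)
  invisible(path)
}

#' RGB color of a pixel
#'
#' @param image a \linkS4class{LeafImage}.
#' @param p length-2 integer (x = column, y = row), 1-based.
#' @return integer length-3 RGB vector.
#' @export
pixelColor <- function(image, p) {
  .checkCoord(p, image)
  c(r = image@r[p[2], p[1]], g = image@g[p[2], p[1]], b = image@b[p[2], p[1]])
}

#' Euclidean distance between two RGB colors
#'
#' Distance in the discrete RGB cube: \code{sqrt(sum((P - Q)^2))}.  The
#' comparison against a tolerance is done in floating point, without
#' rounding.
#'
#' @param p,q length-3 RGB vectors with channels in \code{[0, cmax - 1]}.
#' @param cmax color levels per channel.
#' @return nonnegative numeric distance.
#' @examples
#' colorDistance(c(1, 2, 2), c(0, 0, 0))  # 3
#' @export
colorDistance <- function(p, q, cmax = 256L) {
  .checkColor(p, cmax, "p")
  .checkColor(q, cmax, "q")
  sqrt(sum((as.numeric(p) - as.numeric(q))^2))
}

#' Similarity of two colors at a tolerance ST(x)
#'
#' TRUE when the RGB distance is at most \code{x}.  The relation is
#' reflexive, symmetric, and monotone in \code{x}, but not transitive.
#'
#' @inheritParams colorDistance
#' @param x tolerance upper bound, \code{1 <= x <= cmax - 1}.
#' @return logical(1).
#' @export
pixelSimilar <- function(p, q, x, cmax = 256L) {
  .checkTol(x, cmax)
  colorDistance(p, q, cmax) <= x
}

#' 8-neighborhood of a pixel
#'
#' The vicinity of an in-bounds pixel: its up to eight adjacent coordinates,
#' clipped to the image bounds (border pixels simply have smaller
#' vicinities).  Never contains the pixel itself.
#'
#' @param p length-2 (x, y), 1-based.
#' @param image a \linkS4class{LeafImage}.
#' @return integer matrix with columns x, y; 3, 5 or 8 rows for corner, edge
#'   and interior pixels (0 rows only for a 1 x 1 image).
#' @export
pixelVicinity <- function(p, image) {
  .checkCoord(p, image)
  dx <- c(1L, -1L, 0L, 0L, 1L, 1L, -1L, -1L)
  dy <- c(0L, 0L, 1L, -1L, 1L, -1L, 1L, -1L)
  xs <- p[1] + dx
  ys <- p[2] + dy
  keep <- xs >= 1L & xs <= imageWidth(image) & ys >= 1L & ys <= imageHeight(image)
  cbind(x = as.integer(xs[keep]), y = as.integer(ys[keep]))
}

#' Connectivity of two pixels at a tolerance ST(x)
#'
#' TRUE when the pixels are 8-adjacent and their colors are similar at
#' tolerance \code{x}; the relation is symmetric.
#'
#' @param p,q length-2 (x, y) coordinates, 1-based.
#' @param x tolerance upper bound.
#' @param image a \linkS4class{LeafImage}.
#' @return logical(1).
#' @export
pixelsConnected <- function(p, q, x, image) {
  .checkCoord(p, image)
  .checkCoord(q, image)
  .checkTol(x, colorDepth(image))
  adjacent <- max(abs(p[1] - q[1]), abs(p[2] - q[2])) == 1
  adjacent && pixelSimilar(pixelColor(image, p), pixelColor(image, q), x,
                           colorDepth(image))
}
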