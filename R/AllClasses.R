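#' @title Core S4 classes
#' @name eelgrassArea-classes
#' @description S4 containers for leaf images, grown regions, the length
#'   partition used for cohort grouping, the grouping itself, and the result
#'   of a tolerance sweep.
NULL

#' An RGB raster image of a single leaf
#'
#' Channel intensities are stored as three integer matrices (rows = image
#' rows, columns = image columns) on the discrete scale \code{[0, cmax - 1]}.
#' \code{unp} is the image scale: the number of pixels per millimetre.
#'
#' @slot r,g,b integer matrices of channel intensities.
#' @slot unp numeric(1), pixels per mm; must be > 0.
#' @slot cmax integer(1), number of color levels per channel (256 for 8-bit).
#' @export
setClass("LeafImage",
  representation(r = "matrix", g = "matrix", b = "matrix",
                 unp = "numeric", cmax = "integer"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@r)
    if (!identical(d, dim(object@g)) || !identical(d, dim(object@b)))
      msg <- c(msg, "channel matrices must share dimensions")
    if (length(object@unp) != 1L || !is.finite(object@unp) || object@unp <= 0)
      msg <- c(msg, "unp must be a single positive number")
    if (length(object@cmax) != 1L || object@cmax < 2L)
      msg <- c(msg, "cmax must be a single integer >= 2")
    vals <- range(object@r, object@g, object@b)
    if (vals[1] < 0 || vals[2] > object@cmax - 1L)
      msg <- c(msg, sprintf("channel values must lie in [0, %d]", object@cmax - 1L))
    if (length(msg)) msg else TRUE
  })

#' A connected leaf region grown at a tolerance of similarity
#'
#' @slot mask logical matrix, TRUE for member pixels.
#' @slot contour logical matrix, TRUE for peripheral-contour pixels (members
#'   with at least one 8-neighbor, including off-image positions, outside the
#'   region).
#' @slot seed integer(2), the (x = column, y = row) seed, 1-based.
#' @slot x numeric(1), the tolerance-of-similarity upper bound.
#' @slot unp numeric(1), pixels per mm inherited from the image.
#' @slot flooded logical(1), TRUE when the region reaches all four image
#'   borders (the growth escaped the leaf into the background frame).
#' @export
setClass("LeafRegion",
  representation(mask = "matrix", contour = "matrix", seed = "integer",
                 x = "numeric", unp = "numeric", flooded = "logical"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
    if (!identical(dim(object@mask), dim(object@contour)))
      msg <- c(msg, "mask and contour must share dimensions")
    if (length(object@seed) != 2L) msg <- c(msg, "seed must be length-2 (x, y)")
    if (length(msg)) msg else TRUE
  })

#' A uniform partition of the leaf-length range
#'
#' The interval \code{[0, lmax]} is split into \code{n} half-open intervals
#' \code{I_k = [q(k-1), qk)} of common width \code{q = lmax/n}; the final
#' interval is closed at \code{lmax} so the longest leaf is not orphaned.
#'
#' @slot lmax numeric(1), maximum leaf length (mm).
#' @slot n integer(1), number of intervals.
#' @slot q numeric(1), interval width \code{lmax/n} (mm).
#' @export
setClass("LengthPartition",
  representation(lmax = "numeric", n = "integer", q = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@lmax <= 0) msg <- c(msg, "lmax must be positive")
    if (object@n < 1L) msg <- c(msg, "n must be >= 1")
    if (!isTRUE(all.equal(object@q, object@lmax / object@n)))
      msg <- c(msg, "q must equal lmax/n")
    if (length(msg)) msg else TRUE
  })

#' Leaves assigned to length groups
#'
#' @slot leaves data.frame of leaf records with an added group index \code{k}.
#' @slot groups data.frame with one row per occupied group: \code{k},
#'   \code{n_k}, \code{included} (groups holding fewer than 2 leaves carry no
#'   information for the statistics and are excluded).
#' @slot partition the \linkS4class{LengthPartition} used.
#' @export
setClass("LeafGrouping",
  representation(leaves = "data.frame", groups = "data.frame",
                 partition = "LengthPartition"),
  validity = function(object) {
    msg <- character()
    if (!"k" %in% names(object@leaves)) msg <- c(msg, "leaves must carry a k column")
    need <- c("k", "n_k", "included")
    if (!all(need %in% names(object@groups)))
      msg <- c(msg, "groups must carry k, n_k, included")
    if (length(msg)) msg else TRUE
  })

#' Result of a tolerance-of-similarity sweep over a leaf cohort
#'
#' @slot measurements data.frame of per-leaf, per-tolerance measurements and
#'   errors.
#' @slot stats data.frame with one row per tolerance: cohort deviations,
#'   proportions, and the selection indices.
#' @slot partition the \linkS4class{LengthPartition} used for grouping.
#' @export
setClass("ToleranceSweep",
  representation(measurements = "data.frame", stats = "data.frame",
                 partition = "LengthPartition"))

setMethod("show", "LeafImage", function(object) {
  cat(sprintf("LeafImage: %d x %d px, %.3g px/mm (%.1f x %.1f mm), cmax = %d\n",
              ncol(object@r), nrow(object@r), object@unp,
              ncol(object@r) / object@unp, nrow(object@r) / object@unp,
              object@cmax))
})

setMethod("show", "LeafRegion", function(object) {
  cat(sprintf(paste0("LeafRegion: %d member px (%d on contour), seed (%d, %d),",
                     " ST(%g)%s\n"),
              sum(object@mask), sum(object@contour),
              object@seed[1], object@seed[2], object@x,
              if (object@flooded) " [FLOODED]" else ""))
})

setMethod("show", "LengthPartition", function(object) {
  cat(sprintf("LengthPartition: [0, %g] mm in %d intervals of width q = %g mm\n",
              object@lmax, object@n, object@q))
})

setMethod("show", "LeafGrouping", function(object) {
  g <- object@groups
  cat(sprintf("LeafGrouping: %d leaves, %d/%d groups occupied, %d included in C_G\n",
              nrow(object@leaves), sum(g$n_k > 0L), nrow(g), sum(g$included)))
})

setMethod("show", "ToleranceSweep", function(object) {
  cat(sprintf("ToleranceSweep: %d tolerances x %d leaves\n",
              nrow(object@stats),
              length(unique(object@measurements$leaf_id))))
  print(utils::head(object@stats[, intersect(
    c("x", "lambda_a", "beta_a", "IS", "lambda_amc", "beta_amc", "IS_mc",
      "admissible"), names(object@stats))], 10))
})

#' @describeIn eelgrassArea-classes image width in pixels
#' @param image a \linkS4class{LeafImage}
#' @export
imageWidth <- function(image) ncol(image@r)

#' @describeIn eelgrassArea-classes image height in pixels
#' @export
imageHeight <- function(image) nrow(image@r)

#' @describeIn eelgrassArea-classes image scale, pixels per mm
#' @export
imageScale <- function(image) image@unp

#' @describeIn eelgrassArea-classes number of color levels per channel
#' @export
colorDepth <- function(image) image@cmax

#' Region accessors
#'
#' \code{regionCoords} and \code{contourCoords} return the member /
#' peripheral-contour pixels as two-column integer matrices (x = column,
#' y = row, 1-based); \code{regionSize} the member count; \code{regionMask}
#' the logical membership matrix; \code{isFlooded} whether the growth reached
#' all four image borders.
#'
#' @param region a \linkS4class{LeafRegion}
#' @return see description.
#' @export
regionCoords <- function(region) {
  idx <- which(region@mask, arr.ind = TRUE)
  cbind(x = unname(idx[, 2L]), y = unname(idx[, 1L]))
}

#' @rdname regionCoords
#' @export
contourCoords <- function(region) {
  idx <- which(region@contour, arr.ind = TRUE)
  cbind(x = unname(idx[, 2L]), y = unname(idx[, 1L]))
}

#' @rdname regionCoords
#' @export
regionSize <- function(region) sum(region@mask)

#' @rdname regionCoords
#' @export
regionMask <- function(region) region@mask

#' @rdname regionCoords
#' @export
isFlooded <- function(region) region@flooded
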