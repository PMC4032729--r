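## Morphometry of a grown region: pixel-count length and width, their metric
## conversions l_d = np_l/unp and h_d = np_h/unp, the rectangle-proxy area
## a_d = l_d * h_d, and the Monte Carlo area a_mc = LPN / UPN^2.

#' Pixel extents of a region along its principal axes
#'
#' Length is the pixel extent of the region projected on its principal axis
#' (the major axis of the coordinate covariance; for an axis-aligned leaf
#' this is the bounding-box length).  Width is measured on the cross-section
#' at the midpoint of that extent, mirroring the manual protocol of
#' measuring blade width halfway along the leaf; \code{mode = "max"} instead
#' returns the maximum cross-sectional width.
#'
#' @param region a nonempty \linkS4class{LeafRegion}.
#' @param mode \code{"midpoint"} (default) or \code{"max"}.
#' @return named integer vector \code{c(np_l, np_h)}.
#' @examples
#' img <- LeafImage(array(0L, c(20, 200, 3)), unp = 1)
#' pixelExtents(growRegion(img, x = 1))  # 200 x 20 solid block
#' @export
pixelExtents <- function(region, mode = c("midpoint", "max")) {
  mode <- match.arg(mode)
  if (regionSize(region) == 0L) stop("empty region has no extents")
  xy <- regionCoords(region)
  if (nrow(xy) == 1L) return(c(np_l = 1L, np_h = 1L))
  ctr <- colMeans(xy)
  cc <- sweep(xy, 2L, ctr)
  cv <- cov(cc)
  ev <- eigen(cv, symmetric = TRUE)
  major <- ev$vectors[, 1L]
  minor <- ev$vectors[, 2L]
  u <- cc %*% major
  v <- cc %*% minor
  ru <- range(u)
  np_l <- as.integer(round(ru[2L] - ru[1L])) + 1L
  if (mode == "midpoint") {
    mid <- (ru[1L] + ru[2L]) / 2
    slab <- abs(u - mid) <= 0.5
    rv <- range(v[slab])
    np_h <- as.integer(round(rv[2L] - rv[1L])) + 1L
  } else {
    bins <- round(u - ru[1L])
    np_h <- max(vapply(split(v, bins), function(z)
      as.integer(round(max(z) - min(z))) + 1L, integer(1)))
  }
  c(np_l = np_l, np_h = np_h)
}

#' Convert a pixel count to a metric length
#'
#' \code{l_d = np_l / unp} and \code{h_d = np_h / unp}, where \code{unp} is
#' the number of pixels per measurement unit.
#'
#' @param np nonnegative pixel count.
#' @param unp pixels per mm, > 0.
#' @return length in mm.
#' @export
digitalLength <- function(np, unp) {
  if (length(unp) != 1L || is.na(unp) || unp <= 0) stop("unp must be > 0")
  if (any(np < 0)) stop("pixel count must be nonnegative")
  np / unp
}

#' @rdname digitalLength
#' @export
digitalWidth <- digitalLength

#' Rectangle-proxy leaf area
#'
#' \code{a_d = l_d * h_d}: the length-times-width proxy applied to the
#' image-derived dimensions.  Valid for the near-rectangular blades of
#' eelgrass.
#'
#' @param l_d,h_d nonnegative lengths (mm).
#' @return area in mm^2.
#' @export
digitalArea <- function(l_d, h_d) {
  if (any(l_d < 0) || any(h_d < 0)) stop("dimensions must be nonnegative")
  l_d * h_d
}

#' Monte Carlo leaf area
#'
#' Places sample points over the image frame and estimates the leaf area as
#' \code{a_mc = LPN / UPN^2}, where LPN counts the points whose containing
#' pixel belongs to the region and UPN^2 is the number of points per unit
#' area.  The default sampler is a deterministic uniform grid of pitch
#' 1/UPN (reproducible without seed bookkeeping); \code{sampler = "random"}
#' draws uniform points and requires an explicit seed.
#'
#' @param region a \linkS4class{LeafRegion}.
#' @param UPN sample points per mm, > 0.
#' @param sampler \code{"grid"} (default) or \code{"random"}.
#' @param seed integer seed, required for the random sampler.
#' @return list with \code{a_mc} (mm^2), \code{LPN}, \code{UPN}, \code{n}
#'   (total points placed) and \code{seed} (NA for the grid sampler).
#' @export
monteCarloArea <- function(region, UPN, sampler = c("grid", "random"),
                           seed = NULL) {
  sampler <- match.arg(sampler)
  if (length(UPN) != 1L || is.na(UPN) || UPN <= 0) stop("UPN must be > 0")
  mask <- regionMask(region)
  h <- nrow(mask); w <- ncol(mask)
  unp <- region@unp
  wmm <- w / unp; hmm <- h / unp
  if (sampler == "grid") {
    nx <- max(1L, floor(wmm * UPN))
    ny <- max(1L, floor(hmm * UPN))
    px <- (seq_len(nx) - 0.5) / UPN   # mm from left edge
    py <- (seq_len(ny) - 0.5) / UPN
    cols <- pmin(w, floor(px * unp) + 1L)
    rows <- pmin(h, floor(py * unp) + 1L)
    LPN <- sum(mask[rows, cols, drop = FALSE])
    n <- nx * ny
    used_seed <- NA_integer_
  } else {
    if (is.null(seed)) stop("random sampler requires an explicit seed")
    n <- max(1L, round(wmm * hmm * UPN^2))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    px <- runif(n, 0, wmm)
    py <- runif(n, 0, hmm)
    cols <- pmin(w, floor(px * unp) + 1L)
    rows <- pmin(h, floor(py * unp) + 1L)
    LPN <- sum(mask[cbind(rows, cols)])
    used_seed <- as.integer(seed)
  }
  list(a_mc = LPN / UPN^2, LPN = LPN, UPN = UPN, n = n, seed = used_seed)
}

#' Measure one leaf image at a tolerance ST(x)
#'
#' Runs the full per-leaf pipeline: grow the region from the seed, count
#' pixel extents, convert to metric length/width/area, and estimate the
#' Monte Carlo area.
#'
#' @inheritParams growRegion
#' @param UPN Monte Carlo points per mm; defaults to the image scale.
#' @param sampler,mcSeed passed to \code{\link{monteCarloArea}}.
#' @param mode width mode passed to \code{\link{pixelExtents}}.
#' @return one-row data.frame: \code{x, np_l, np_h, l_d, h_d, a_d, LPN, UPN,
#'   a_mc, seed, region_px, flooded}.
#' @export
measureLeaf <- function(image, x, seed = NULL, UPN = imageScale(image),
                        sampler = "grid", mcSeed = NULL,
                        mode = "midpoint") {
  region <- growRegion(image, x = x, seed = seed)
  ext <- pixelExtents(region, mode = mode)
  unp <- imageScale(image)
  l_d <- digitalLength(ext[["np_l"]], unp)
  h_d <- digitalWidth(ext[["np_h"]], unp)
  mc <- monteCarloArea(region, UPN = UPN, sampler = sampler, seed = mcSeed)
  data.frame(x = x, np_l = ext[["np_l"]], np_h = ext[["np_h"]],
             l_d = l_d, h_d = h_d, a_d = digitalArea(l_d, h_d),
             LPN = mc$LPN, UPN = mc$UPN, a_mc = mc$a_mc,
             mc_seed = mc$seed, region_px = regionSize(region),
             flooded = isFlooded(region))
}
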