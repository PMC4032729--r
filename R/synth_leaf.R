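## Synthetic leaf-image generator: ribbon-like blades with known ground
## truth on a contrasting background, plus a parameterized "humidity halo"
## of intermediate-color pixels along the contour — the noise mechanism the
## tolerance-selection procedure must detect.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

.dilate8 <- function(mask, times) {
  if (times < 1L) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  for (i in seq_len(times)) {
    pad <- matrix(FALSE, h + 2L, w + 2L)
    pad[2:(h + 1L), 2:(w + 1L)] <- mask
    acc <- mask
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      acc <- acc | pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
    }
    mask <- acc
  }
  mask
}

#' Render a synthetic eelgrass leaf image with ground truth
#'
#' Draws a ribbon-like blade — an axis-aligned trapezoid (optional linear
#' taper toward the tip and sinusoidal midline curvature) — on a uniform
#' background, optionally surrounded by a humidity halo: a ring of pixels
#' whose colors lie strictly between the leaf and background colors in RGB
#' space, emulating the intermediate tones that leaf water content adds
#' along the contour.  Ground truth follows the manual protocol: width is
#' taken halfway along the blade, and the observed area is the
#' length-times-width proxy \code{a_o = l_o * h_o} (which for this shape
#' equals the true trapezoid area).
#'
#' @param length_mm blade length (mm), <= 460 by default (the longest leaf
#'   reported for the species) unless \code{force = TRUE}.
#' @param width_mm blade width at the base (mm), in \code{[1.5, 12]} (the
#'   reported variation range) unless \code{force = TRUE}.
#' @param taper fraction in \code{[0, 1)} by which the width shrinks at the
#'   tip; 0 gives a rectangle, for which the proxy is exact.
#' @param curvature sinusoidal midline amplitude (mm).
#' @param leafColor,bgColor RGB vectors in \code{[0, cmax - 1]}.
#' @param haloRange fractions (low, high) of the leaf-to-background segment
#'   from which halo colors are drawn; must lie strictly inside (0, 1) so
#'   halo tones sit strictly between leaf and background.
#' @param haloWidth halo ring thickness in pixels (0 disables).
#' @param jitter intra-leaf per-channel color jitter, uniform integers in
#'   \code{[-jitter, jitter]}.
#' @param unp pixels per mm (default 10, about a 254-dpi flatbed scan).
#' @param seed integer seed; rendering is bit-reproducible for a fixed seed.
#' @param marginPx background margin around the blade.
#' @param cmax color levels per channel.
#' @param force allow dimensions outside the validated ranges.
#' @return list with \code{image} (\linkS4class{LeafImage}), ground truth
#'   \code{l_o, h_o, a_o} (mm, mm, mm^2), \code{pixel_area} (mm^2, exact
#'   rasterized area), \code{mask} (logical), \code{seed_x, seed_y} (a pixel
#'   on the midline, guaranteed inside the blade),
#'   \code{leaf_halo_distance} (RGB distance from leaf color to the nearest
#'   admissible halo tone), \code{halo_bg_distance} (distance from the
#'   farthest halo tone to the background, where flooding begins) and
#'   \code{leaf_bg_distance}.
#' @export
renderLeaf <- function(length_mm, width_mm, taper = 0, curvature = 0,
                       leafColor = c(30, 90, 40), bgColor = c(235, 235, 240),
                       haloRange = c(0.30, 0.55), haloWidth = 0, jitter = 0,
                       unp = 10, seed = 1, marginPx = NULL, cmax = 256L,
                       force = FALSE) {
  if (!force && (width_mm < 1.5 || width_mm > 12))
    stop("width_mm outside the validated range [1.5, 12]; use force = TRUE to override")
  if (!force && (length_mm <= 0 || length_mm > 460))
    stop("length_mm outside the validated range (0, 460]; use force = TRUE to override")
  if (taper < 0 || taper >= 1) stop("taper must lie in [0, 1)")
  .checkColor(leafColor, cmax, "leafColor")
  .checkColor(bgColor, cmax, "bgColor")
  if (haloWidth > 0 &&
      (haloRange[1] <= 0 || haloRange[2] >= 1 || haloRange[1] > haloRange[2]))
    stop("haloRange must lie strictly inside (0, 1): halo colors must sit between leaf and background")

  if (is.null(marginPx)) marginPx <- max(8L, haloWidth + 4L)
  npl <- round(length_mm * unp)
  W <- npl + 2L * marginPx
  H <- round(width_mm * unp) + 2L * round(abs(curvature) * unp) + 2L * marginPx

  cols <- marginPx + seq_len(npl)
  u_mm <- (cols - 0.5 - marginPx) / unp               # position along blade
  # quarter-pixel midline offset: keeps the midline off the pixel grid so
  # rasterized width counts are not forced to a single parity
  ymid <- H / 2 + 0.25 + curvature * sin(pi * u_mm / length_mm) * unp
  hw_px <- (width_mm / 2) * (1 - taper * u_mm / length_mm) * unp
  rowc <- seq_len(H) - 0.5
  mask <- matrix(FALSE, H, W)
  mask[, cols] <- abs(outer(rowc, ymid, "-")) <
    matrix(hw_px, H, length(cols), byrow = TRUE)

  d_lb <- sqrt(sum((as.numeric(leafColor) - as.numeric(bgColor))^2))
  r <- matrix(bgColor[1], H, W); g <- matrix(bgColor[2], H, W)
  b <- matrix(bgColor[3], H, W)
  halo <- matrix(FALSE, H, W)
  .withSeed(seed, {
    nin <- sum(mask)
    jit <- function(ch) {
      v <- rep(ch, nin)
      if (jitter > 0) v <- v + sample.int(2L * jitter + 1L, nin, replace = TRUE) -
          (jitter + 1L)
      pmin(pmax(v, 0), cmax - 1L)
    }
    r[mask] <- jit(leafColor[1])
    g[mask] <- jit(leafColor[2])
    b[mask] <- jit(leafColor[3])
    if (haloWidth > 0) {
      halo <- .dilate8(mask, haloWidth) & !mask
      nh <- sum(halo)
      tt <- runif(nh, haloRange[1], haloRange[2])
      r[halo] <- round(leafColor[1] + tt * (bgColor[1] - leafColor[1]))
      g[halo] <- round(leafColor[2] + tt * (bgColor[2] - leafColor[2]))
      b[halo] <- round(leafColor[3] + tt * (bgColor[3] - leafColor[3]))
    }
  })
  arr <- array(c(r, g, b), c(H, W, 3L))
  img <- LeafImage(arr, unp = unp, cmax = cmax)

  h_o <- width_mm * (1 - taper / 2)                  # width halfway along
  midCol <- marginPx + max(1L, round(npl / 2))
  list(image = img,
       l_o = length_mm, h_o = h_o, a_o = length_mm * h_o,
       pixel_area = sum(mask) / unp^2,
       mask = mask, halo_mask = halo,
       seed_x = midCol,
       seed_y = round(H / 2 + curvature * sin(pi / 2) * unp),
       leaf_halo_distance = haloRange[1] * d_lb,
       halo_bg_distance = (1 - haloRange[2]) * d_lb,
       leaf_bg_distance = d_lb)
}

#' Generate a cohort of synthetic leaves with a manifest
#'
#' Samples blade lengths and widths uniformly from the stated ranges,
#' renders each leaf (all randomness flows from the single cohort seed),
#' and returns — or writes as PNG files plus a manifest CSV — a cohort
#' ready for \code{\link{sweepCohort}}.
#'
#' @param nLeaves number of leaves, >= 1.
#' @param seed integer cohort seed.
#' @param lengthRange,widthRange sampling ranges (mm); each must span a
#'   positive width (a degenerate range is an error).
#' @param outDir optional directory; when given, images are written as
#'   \code{leaf_###.png} and a \code{manifest.csv} alongside, and the
#'   manifest's \code{image_path} points at them.  When NULL the rendered
#'   images are kept in memory in the returned \code{images} list.
#' @param ... further arguments passed to \code{\link{renderLeaf}}
#'   (\code{taper, curvature, haloWidth, jitter, unp, leafColor, bgColor,
#'   haloRange, ...}).
#' @return list with \code{manifest} (data.frame: leaf_id, image_path,
#'   seed_x, seed_y, l_o, h_o, unp), \code{images} (named list of
#'   \linkS4class{LeafImage}, NULL when written to disk), \code{truth}
#'   (per-leaf ground-truth data.frame incl. exact pixel areas), and the
#'   color-geometry distances of the renderer.
#' @export
generateCohort <- function(nLeaves = 50, seed = 1,
                           lengthRange = c(20, 300), widthRange = c(1.5, 12),
                           outDir = NULL, ...) {
  if (nLeaves < 1) stop("nLeaves must be >= 1")
  if (diff(lengthRange) <= 0 || diff(widthRange) <= 0)
    stop("degenerate length or width distribution")
  dots <- list(...)
  unp <- if (!is.null(dots$unp)) dots$unp else 10

  drawn <- .withSeed(seed, list(
    lengths = runif(nLeaves, lengthRange[1], lengthRange[2]),
    widths = runif(nLeaves, widthRange[1], widthRange[2]),
    leafSeeds = sample.int(.Machine$integer.max - 1L, nLeaves)))

  ids <- sprintf("leaf_%03d", seq_len(nLeaves))
  images <- if (is.null(outDir)) stats::setNames(vector("list", nLeaves), ids)
  rows <- vector("list", nLeaves)
  truth <- vector("list", nLeaves)
  geom <- NULL
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  for (i in seq_len(nLeaves)) {
    lf <- do.call(renderLeaf, c(list(length_mm = drawn$lengths[i],
                                     width_mm = drawn$widths[i],
                                     seed = drawn$leafSeeds[i]), dots))
    path <- NA_character_
    if (is.null(outDir)) {
      images[[ids[i]]] <- lf$image
    } else {
      path <- file.path(outDir, paste0(ids[i], ".png"))
      writeLeafImagePNG(lf$image, path)
    }
    rows[[i]] <- data.frame(leaf_id = ids[i], image_path = path,
                            seed_x = lf$seed_x, seed_y = lf$seed_y,
                            l_o = lf$l_o, h_o = lf$h_o, unp = unp,
                            render_seed = drawn$leafSeeds[i])
    truth[[i]] <- data.frame(leaf_id = ids[i], a_o = lf$a_o,
                             pixel_area = lf$pixel_area)
    geom <- lf[c("leaf_halo_distance", "halo_bg_distance", "leaf_bg_distance")]
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(outDir))
    write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  c(list(manifest = manifest,
         images = if (is.null(outDir)) images else NULL,
         truth = do.call(rbind, truth)),
    geom)
}
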