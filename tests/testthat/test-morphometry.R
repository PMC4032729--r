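# Pixel extents, metric conversions and the Monte Carlo area estimator.

rectRegion <- function(w, h, unp = 1, pad = 2) {
  idx <- matrix(2L, h + 2 * pad, w + 2 * pad)
  idx[pad + seq_len(h), pad + seq_len(w)] <- 1L
  img <- paletteImage(idx, list(c(0, 0, 0), c(255, 255, 255)), unp = unp)
  growRegion(img, x = 50, seed = c(pad + 1, pad + 1))
}

test_that("pixelExtents recovers rectangle dimensions and single pixels", {
  expect_equal(pixelExtents(rectRegion(200, 20)), c(np_l = 200L, np_h = 20L))
  expect_equal(pixelExtents(rectRegion(20, 200)), c(np_l = 200L, np_h = 20L))

  idx <- matrix(2L, 3, 3); idx[2, 2] <- 1L
  img <- paletteImage(idx, list(c(0, 0, 0), c(255, 255, 255)))
  single <- growRegion(img, x = 50, seed = c(2, 2))
  expect_equal(pixelExtents(single), c(np_l = 1L, np_h = 1L))
})

test_that("midpoint width ignores a notch away from the midline", {
  pad <- 2
  idx <- matrix(2L, 9 + 2 * pad, 40 + 2 * pad)
  idx[pad + 1:9, pad + 1:40] <- 1L
  idx[pad + 1:2, pad + 35:36] <- 2L   # notch near the tip, off the midpoint
  img <- paletteImage(idx, list(c(0, 0, 0), c(255, 255, 255)))
  reg <- growRegion(img, x = 50, seed = c(pad + 5, pad + 5))
  ext <- pixelExtents(reg)
  expect_equal(ext[["np_l"]], 40L)
  expect_equal(ext[["np_h"]], 9L)
  # max mode reports the widest cross-section regardless of position
  expect_equal(pixelExtents(reg, mode = "max")[["np_h"]], 9L)
})

test_that("digital length/width/area are exact quotients and products", {
  expect_identical(digitalLength(100, 10), 10)
  expect_identical(digitalLength(460, 1), 460)
  expect_identical(digitalLength(0, 10), 0)
  expect_identical(digitalWidth(20, 20), 1)
  expect_identical(digitalWidth(6, 1), 6)
  expect_identical(digitalWidth(12, 1), 12)
  expect_identical(digitalArea(10, 1), 10)
  expect_identical(digitalArea(0, 5), 0)
  expect_identical(digitalArea(230, 3.5), 805)
  expect_error(digitalLength(10, 0), "unp")
  expect_error(digitalArea(-1, 1), "nonnegative")
})

test_that("grid Monte Carlo is exact on a unit square and bounded by perimeter/UPN", {
  unp <- 8
  reg <- rectRegion(unp, unp, unp = unp)        # one full mm^2
  mc <- monteCarloArea(reg, UPN = unp)
  expect_identical(mc$a_mc, 1)

  reg <- rectRegion(10 * unp, 2 * unp, unp = unp)  # 10 mm x 2 mm
  UPN <- 4 * unp
  mc <- monteCarloArea(reg, UPN = UPN)
  exact <- regionSize(reg) / unp^2
  expect_lt(abs(mc$a_mc - exact), 2 * (10 + 2) / UPN)
  expect_error(monteCarloArea(reg, UPN = 0), "UPN")
})

test_that("grid Monte Carlo converges to the pixel-count area as UPN grows", {
  unp <- 6
  lf <- renderLeaf(30, 5, taper = 0.3, unp = unp, seed = 2)
  reg <- growRegion(lf$image, x = 48, seed = c(lf$seed_x, lf$seed_y))
  exact <- regionSize(reg) / unp^2
  errs <- vapply(c(6, 12, 24, 48), function(UPN)
    abs(monteCarloArea(reg, UPN = UPN)$a_mc - exact), numeric(1))
  perim <- 2 * (30 + 5)
  expect_true(all(errs <= perim / c(6, 12, 24, 48)))
  expect_lt(errs[4], errs[1] + 1e-9)
})

test_that("random-sampler spread stays within the binomial standard error", {
  unp <- 4
  reg <- rectRegion(20 * unp, 3 * unp, unp = unp)  # 20 x 3 mm leaf
  frameA <- ncol(regionMask(reg)) * nrow(regionMask(reg)) / unp^2
  UPN <- 4
  draws <- vapply(1:30, function(s)
    monteCarloArea(reg, UPN = UPN, sampler = "random", seed = s)$a_mc,
    numeric(1))
  n <- monteCarloArea(reg, UPN = UPN, sampler = "random", seed = 1)$n
  p <- (regionSize(reg) / unp^2) / frameA
  se <- sqrt(p * (1 - p) / n) * frameA
  expect_lt(abs(mean(draws) - 60), 3 * se / sqrt(30) + 1)
  expect_lt(sd(draws), 1.6 * se)
  expect_error(monteCarloArea(reg, UPN = UPN, sampler = "random"), "seed")
})

test_that("rectangle a_d equals the pixel-count area; tapered blades are over-covered", {
  unp <- 10
  lf <- renderLeaf(50, 6, unp = unp, seed = 3)
  reg <- growRegion(lf$image, x = 48, seed = c(lf$seed_x, lf$seed_y))
  ext <- pixelExtents(reg)
  a_d <- digitalArea(ext[["np_l"]] / unp, ext[["np_h"]] / unp)
  expect_equal(a_d, regionSize(reg) / unp^2, tolerance = 1e-12)

  tp <- renderLeaf(50, 6, taper = 0.4, unp = unp, seed = 4)
  reg <- growRegion(tp$image, x = 48, seed = c(tp$seed_x, tp$seed_y))
  pixelA <- regionSize(reg) / unp^2
  # max-width rectangle strictly over-covers a tapered blade
  extMax <- pixelExtents(reg, mode = "max")
  expect_gt(digitalArea(extMax[["np_l"]] / unp, extMax[["np_h"]] / unp), pixelA)
  # midpoint width equals the trapezoid's mean width, so a_d tracks the area
  ext <- pixelExtents(reg)
  expect_equal(digitalArea(ext[["np_l"]] / unp, ext[["np_h"]] / unp), pixelA,
               tolerance = 0.02)
})

test_that("doubling the scale moves l_d and h_d by at most a pixel quantum", {
  for (s in 1:3) {
    a <- renderLeaf(37.3, 4.7, unp = 5, seed = s)
    b <- renderLeaf(37.3, 4.7, unp = 10, seed = s)
    ra <- growRegion(a$image, x = 48, seed = c(a$seed_x, a$seed_y))
    rb <- growRegion(b$image, x = 48, seed = c(b$seed_x, b$seed_y))
    ea <- pixelExtents(ra); eb <- pixelExtents(rb)
    expect_lt(abs(ea[["np_l"]] / 5 - eb[["np_l"]] / 10), 1 / 5 + 1e-9)
    expect_lt(abs(ea[["np_h"]] / 5 - eb[["np_h"]] / 10), 1 / 5 + 1e-9)
  }
})
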