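# Fixtures built in code: tiny images from palette index matrices, random
# test images, and an independent connected-component oracle (explicit edge
# enumeration + igraph), never the package's own flood fill.

paletteImage <- function(idx, palette, unp = 1) {
  # idx: H x W matrix of 1-based palette indices; palette: list of RGB triples
  h <- nrow(idx); w <- ncol(idx)
  arr <- array(0L, c(h, w, 3L))
  for (ch in 1:3)
    arr[, , ch] <- matrix(vapply(palette, `[`, numeric(1), ch)[idx], h, w)
  LeafImage(arr, unp = unp)
}

uniformImage <- function(h, w, color = c(10, 10, 10), unp = 1)
  paletteImage(matrix(1L, h, w), list(color), unp = unp)

randomImage <- function(maxSide = 8, maxColors = 4, seed) {
  set.seed(seed)
  h <- sample(2:maxSide, 1)
  w <- sample(2:maxSide, 1)
  ncol_ <- sample(2:maxColors, 1)
  palette <- replicate(ncol_, sample(0:255, 3, replace = TRUE),
                       simplify = FALSE)
  idx <- matrix(sample.int(ncol_, h * w, replace = TRUE), h, w)
  paletteImage(idx, palette)
}

# Independent oracle: build the similarity graph by exhaustive enumeration of
# adjacent pixel pairs, take igraph components, return the sorted linear
# indices (column-major) of the component containing the seed.
oracleComponent <- function(image, seed, x) {
  W <- imageWidth(image); H <- imageHeight(image)
  id <- function(cx, cy) (cx - 1L) * H + cy
  from <- integer(0); to <- integer(0)
  for (cx in seq_len(W)) for (cy in seq_len(H)) {
    p <- pixelColor(image, c(cx, cy))
    for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
      nx <- cx + d[1]; ny <- cy + d[2]
      if (nx >= 1 && nx <= W && ny >= 1 && ny <= H) {
        q <- pixelColor(image, c(nx, ny))
        if (sqrt(sum((as.numeric(p) - as.numeric(q))^2)) <= x) {
          from <- c(from, id(cx, cy)); to <- c(to, id(nx, ny))
        }
      }
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = W * H, directed = FALSE)
  memb <- igraph::components(g)$membership
  sort(which(memb == memb[id(seed[1], seed[2])]))
}

regionIndices <- function(region) {
  xy <- regionCoords(region)
  sort(as.integer((xy[, "x"] - 1L) * nrow(regionMask(region)) + xy[, "y"]))
}
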