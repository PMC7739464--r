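# Key-region selection by coefficient of variation and smooth/texture
# classification of the 8x8 grid by MSE against a threshold T.

#' Coefficient of variation of a block
#'
#' Computes mu (arithmetic mean), sigma (population standard deviation,
#' 1/N form) and C_v = sigma / mu of a pixel block. An all-black block
#' (mu = 0) has C_v defined as 0 so that empty background can never win the
#' key-region argmax.
#'
#' @param block a \linkS4class{GrayImage}.
#' @param tile optional 1-based (row, col) anchor recorded in the result.
#' @return a \linkS4class{KeyRegionStats}.
#' @examples
#' coefficientOfVariation(grayImage(matrix(c(0, 255, 255, 0), 2)))  # Cv = 1
#' @export
coefficientOfVariation <- function(block, tile = c(1L, 1L)) {
  stopifnot(is(block, "GrayImage"))
  px <- block@pixels
  n <- length(px)
  mu <- mean(px)
  sigma <- sqrt(sum((px - mu)^2) / n)
  new("KeyRegionStats", tile = as.integer(tile), size = nrow(px),
      mu = mu, sigma = sigma, cv = if (mu > 0) sigma / mu else 0,
      nPixels = n)
}

#' Mean squared error of a block about its own mean
#'
#' MSE = (1/mn) sum over the block of (I - Iave)^2 with Iave the block mean,
#' i.e. the population variance of the block. Zero for constant blocks.
#'
#' @param block a \linkS4class{GrayImage}.
#' @return non-negative numeric scalar.
#' @export
blockMSE <- function(block) {
  stopifnot(is(block, "GrayImage"))
  px <- block@pixels
  mean((px - mean(px))^2)
}

# Per-tile mean and variance over a full b x b grid, vectorized. Returns
# nTileRow x nTileCol matrices; margin pixels beyond the grid are ignored.
.tile_moments <- function(px, b) {
  d <- dim(px)
  ntr <- d[1L] %/% b; ntc <- d[2L] %/% b
  core <- px[seq_len(ntr * b), seq_len(ntc * b), drop = FALSE]
  rowTile <- rep(seq_len(ntr), each = b)
  colTile <- rep(seq_len(ntc), each = b)
  sums  <- t(rowsum(t(rowsum(core, rowTile)), colTile))
  sqs   <- t(rowsum(t(rowsum(core^2, rowTile)), colTile))
  dimnames(sums) <- dimnames(sqs) <- NULL
  mu <- sums / (b * b)
  list(mean = mu, var = sqs / (b * b) - mu^2)
}

.stats_for_tile <- function(image, tile, size) {
  coefficientOfVariation(extractBlock(image, tile, size), tile = tile)
}

#' Select the key region automatically
#'
#' Splits the image into non-overlapping \code{size} x \code{size} tiles
#' (trailing margins excluded) and returns the tile with the largest
#' coefficient of variation, i.e. the most information-rich candidate lesion
#' block. Ties are broken deterministically by row-major tile order.
#'
#' @param image a \linkS4class{GrayImage} admitting at least one full tile.
#' @param size key-region side in pixels (default 160).
#' @return a \linkS4class{KeyRegionStats} for the winning tile.
#' @export
selectKeyRegion <- function(image, size = 160L) {
  stopifnot(is(image, "GrayImage"))
  size <- as.integer(size)
  d <- dim(image@pixels)
  if (min(d) < size)
    .rc_error("roicrypt_bounds_error",
              "image %d x %d is smaller than the %d x %d key region",
              d[1L], d[2L], size, size)
  mo <- .tile_moments(image@pixels, size)
  cv <- sqrt(pmax(mo$var, 0)) / ifelse(mo$mean > 0, mo$mean, Inf)
  # row-major first maximum
  cvRM <- as.vector(t(cv))
  k <- which.max(cvRM)
  ntc <- ncol(cv)
  tr <- (k - 1L) %/% ntc + 1L
  tc <- (k - 1L) %% ntc + 1L
  .stats_for_tile(image, c((tr - 1L) * size + 1L, (tc - 1L) * size + 1L), size)
}

#' Override the key region manually
#'
#' Clinician-facing escape hatch: returns the statistics of a user-supplied
#' tile, bypassing the automatic argmax. The anchor need not lie on the
#' 160-grid; any in-bounds placement is accepted and downstream stages anchor
#' around it.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param tile integer(2), 1-based (row, col) anchor.
#' @param size key-region side in pixels (default 160).
#' @return a \linkS4class{KeyRegionStats}.
#' @export
overrideKeyRegion <- function(image, tile, size = 160L) {
  stopifnot(is(image, "GrayImage"))
  size <- as.integer(size)
  tile <- .check_tile(image, tile, size)
  .stats_for_tile(image, tile, size)
}

# logical tile matrix: grid tiles intersecting the key rectangle
.key_overlap_mask <- function(ntr, ntc, b, keyRect) {
  m <- matrix(FALSE, ntr, ntc)
  if (length(keyRect) == 3L) {
    r0 <- keyRect[1L]; c0 <- keyRect[2L]; ks <- keyRect[3L]
    tr <- which((seq_len(ntr) - 1L) * b + b >= r0 & (seq_len(ntr) - 1L) * b + 1L <= r0 + ks - 1L)
    tc <- which((seq_len(ntc) - 1L) * b + b >= c0 & (seq_len(ntc) - 1L) * b + 1L <= c0 + ks - 1L)
    m[tr, tc] <- TRUE
  }
  m
}

#' Classify grid blocks into smooth and texture areas
#'
#' Computes the MSE of every tile of the full-image \code{blockSize} grid and
#' labels tiles with MSE > T as texture (embeddable) and MSE <= T as smooth.
#' Tiles with MSE > 0 form the scramble set. Tiles overlapping the key
#' region are excluded from both the embeddable and the scramble sets: that
#' area is replaced by the code block, not used as a carrier.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param threshold the texture threshold T (>= 0).
#' @param keyRect integer(3) (row, col, size) of the key region, or NULL.
#' @param blockSize grid tile side (default 8).
#' @return a \linkS4class{TextureMap}.
#' @export
classifyBlocks <- function(image, threshold, keyRect = NULL, blockSize = 8L) {
  stopifnot(is(image, "GrayImage"), threshold >= 0)
  b <- as.integer(blockSize)
  mo <- .tile_moments(image@pixels, b)
  mse <- pmax(mo$var, 0)
  keyRect <- if (is.null(keyRect)) integer(0) else as.integer(keyRect)
  ov <- .key_overlap_mask(nrow(mse), ncol(mse), b, keyRect)
  new("TextureMap", blockSize = b, mse = mse, threshold = as.numeric(threshold),
      embeddable = (mse > threshold) & !ov,
      scramble = (mse > 0) & !ov,
      keyRect = keyRect)
}
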