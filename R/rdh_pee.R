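# Reversible data hiding by prediction-error expansion (PEE).
#
# Each pixel is predicted as the mean u of its four horizontal/vertical
# neighbors (the diamond predictor) and the integer prediction error is
# d = floor(u - v). Errors inside the selection range [p, q] are expanded to
# D = 2d + b to carry one payload bit b; errors outside are histogram-shifted
# by a constant (q+1 upward, p downward) to keep the two populations
# disjoint. The stego pixel is v' = v + (d - D), which is exactly invertible:
# re-predicting on the stego image returns D, and v = v' + (D - d).
#
# Embedding runs in two global checkerboard passes -- the even layer
# ((row + col) even) first, then the odd layer -- so that each target's four
# predictors are in the same state at embedding and at extraction time
# (extraction replays the layers in reverse). Within a pass, targets are
# visited in canonical column-major pixel order. Pixels whose modified value
# would leave [0, 255] are recorded in a location map and left untouched.

# -- elementary operations ------------------------------------------------

#' Diamond prediction of one pixel
#'
#' Predicts pixel (row, col) as the mean of its four horizontal/vertical
#' neighbors and returns the integer prediction error d = floor(u - v)
#' (floor toward minus infinity). Pixels on the image border lack a full
#' diamond and are flagged not embeddable rather than raising an error.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param row,col 1-based pixel position.
#' @return list with elements \code{embeddable}, \code{u} (predicted value)
#'   and \code{d} (prediction error; NA when not embeddable).
#' @examples
#' img <- grayImage(rbind(c(0, 10, 0), c(20, 20, 30), c(0, 40, 0)))
#' predictPixel(img, 2, 2)  # u = 25, d = 5
#' @export
predictPixel <- function(image, row, col) {
  stopifnot(is(image, "GrayImage"))
  px <- image@pixels
  d <- dim(px)
  if (row <= 1L || row >= d[1L] || col <= 1L || col >= d[2L])
    return(list(embeddable = FALSE, u = NA_real_, d = NA_integer_))
  s <- px[row - 1L, col] + px[row + 1L, col] + px[row, col - 1L] + px[row, col + 1L]
  list(embeddable = TRUE, u = s / 4,
       d = (s - 4L * px[row, col]) %/% 4L)
}

#' Map a prediction error to its embedded/shifted value
#'
#' The three-case PEE mapping: errors in [p, q] become 2d + b (carrying bit
#' b), errors above q shift up by q + 1, errors below p shift by p. With the
#' default range [-2, 2] the two shifts have magnitude 3 and 2.
#'
#' @param d integer prediction error(s).
#' @param bit payload bit(s) in {0, 1}; consumed only where d is in range.
#' @param p,q error selection range, p <= 0 <= q.
#' @return integer vector of mapped values D.
#' @examples
#' mapError(5, p = -2, q = 2)        # 8: shift of magnitude 3
#' mapError(-4, p = -2, q = 2)       # -6: shift of magnitude 2
#' mapError(1, bit = 1, p = -2, q = 2)  # 3 = 2*1 + 1
#' @export
mapError <- function(d, bit = 0L, p = -2L, q = 2L) {
  d <- as.integer(d); p <- as.integer(p); q <- as.integer(q)
  stopifnot(p <= 0L, q >= 0L)
  bit <- rep_len(as.integer(bit), length(d))
  if (any(bit[d >= p & d <= q] %in% c(0L, 1L) == FALSE))
    .rc_error("roicrypt_format_error", "bits must be 0 or 1")
  ifelse(d > q, d + q + 1L, ifelse(d < p, d + p, 2L * d + bit))
}

#' Invert the PEE error mapping
#'
#' Exact inverse of \code{\link{mapError}}: values in [2p, 2q+1] yield
#' d = floor(D / 2) and the carried bit b = D mod 2 (mathematical mod, so b
#' is in {0, 1} for negative D too); shifted values yield the original error
#' and no bit.
#'
#' @param D integer mapped value(s).
#' @param p,q error selection range used at embedding.
#' @return list with integer vector \code{d} and integer vector \code{bit}
#'   (NA where the value carried no bit).
#' @examples
#' unmapError(-3, p = -2, q = 2)  # d = -2, bit = 1
#' unmapError(8, p = -2, q = 2)   # d = 5, no bit
#' @export
unmapError <- function(D, p = -2L, q = 2L) {
  D <- as.integer(D); p <- as.integer(p); q <- as.integer(q)
  stopifnot(p <= 0L, q >= 0L)
  inr <- D >= 2L * p & D <= 2L * q + 1L
  list(d = ifelse(inr, D %/% 2L, ifelse(D > 2L * q + 1L, D - q - 1L, D - p)),
       bit = ifelse(inr, D %% 2L, NA_integer_))
}

# -- target enumeration ---------------------------------------------------

# Linear (column-major, ascending) indices of embedding targets of one
# checkerboard parity: pixels of embeddable tiles whose full diamond lies
# inside the image and does not touch the key rectangle.
.pee_targets <- function(dm, tileMask, b, keyRect, parity) {
  H <- dm[1L]; W <- dm[2L]
  ntr <- nrow(tileMask); ntc <- ncol(tileMask)
  pm <- matrix(FALSE, H, W)
  pm[seq_len(ntr * b), seq_len(ntc * b)] <-
    tileMask[rep(seq_len(ntr), each = b), rep(seq_len(ntc), each = b)]
  pm[c(1L, H), ] <- FALSE
  pm[, c(1L, W)] <- FALSE
  if (length(keyRect) == 3L) {
    r0 <- keyRect[1L]; c0 <- keyRect[2L]; ks <- keyRect[3L]
    rIn <- max(1L, r0):min(H, r0 + ks - 1L)
    cIn <- max(1L, c0):min(W, c0 + ks - 1L)
    pm[max(1L, r0 - 1L):min(H, r0 + ks), cIn] <- FALSE  # vertical predictor in key rect
    pm[rIn, max(1L, c0 - 1L):min(W, c0 + ks)] <- FALSE  # horizontal predictor in key rect
  }
  par <- (.row(dm) + .col(dm)) %% 2L
  which(pm & par == parity)
}

# -- embedding ------------------------------------------------------------

# One checkerboard pass. Processes targets in order until the available bits
# are exhausted; pixels at risk of leaving [0, 255] are moved to the skip set
# (location map) by fixed-point iteration, since the skip set shifts the bit
# assignment which in turn decides which pixels are at risk.
.pee_embed_pass <- function(px, H, targets, p, q, bits, offset) {
  n <- length(targets)
  avail <- length(bits) - offset
  if (n == 0L || avail == 0L)
    return(list(px = px, used = 0L, skip = integer(0)))
  v <- px[targets]
  s <- px[targets - 1L] + px[targets + 1L] + px[targets - H] + px[targets + H]
  dd <- (s - 4L * v) %/% 4L
  inr <- dd >= p & dd <= q
  shiftDelta <- integer(n)
  shiftDelta[dd > q] <- -(q + 1L)
  shiftDelta[dd < p] <- -p
  skip <- logical(n)
  repeat {
    consume <- inr & !skip
    cum <- cumsum(consume)
    if (cum[n] >= avail) {
      nUse <- avail
      stopPos <- match(avail, cum)       # pixel consuming the final bit
    } else {
      nUse <- cum[n]
      stopPos <- n                        # stream not exhausted: full layer
    }
    delta <- shiftDelta
    if (nUse > 0L) {
      cIdx <- which(consume)[seq_len(nUse)]
      bv <- bits[offset + seq_len(nUse)]
      delta[cIdx] <- -(dd[cIdx] + bv)     # v' = v + d - (2d + b)
    }
    act <- seq_len(stopPos)
    newv <- ifelse(skip[act], v[act], v[act] + delta[act])
    over <- act[!skip[act] & (newv < 0L | newv > 255L)]
    if (length(over) == 0L) {
      px[targets[act]] <- newv
      return(list(px = px, used = nUse, skip = targets[skip]))
    }
    skip[over] <- TRUE
  }
}

.pee_embed <- function(px, tileMask, b, keyRect, p, q, bits) {
  H <- nrow(px)
  skipAll <- integer(0)
  used <- 0L
  nEven <- 0L
  for (parity in c(0L, 1L)) {
    tg <- .pee_targets(dim(px), tileMask, b, keyRect, parity)
    res <- .pee_embed_pass(px, H, tg, p, q, bits, used)
    px <- res$px
    skipAll <- c(skipAll, res$skip)
    if (parity == 0L) nEven <- res$used
    used <- used + res$used
  }
  list(px = px, used = used, nEven = nEven,
       skip = sort(skipAll), shortfall = used < length(bits))
}

#' Embed a bitstream reversibly into the texture area
#'
#' Embeds \code{stream} into the embeddable tiles of \code{textureMap} by
#' prediction-error expansion, histogram-shifting out-of-range errors, and
#' returns the stego image together with the complete side information needed
#' for exact extraction. Smooth tiles are never modified.
#'
#' @param image the carrier \linkS4class{GrayImage}.
#' @param textureMap a \linkS4class{TextureMap} (or a logical tile matrix
#'   combined with \code{keyRect}/\code{blockSize}) defining the embeddable set.
#' @param stream integer vector of payload bits in {0, 1}.
#' @param errorRange integer(2), the selection range c(p, q); default c(-2, 2).
#' @param keyRect,blockSize used only when \code{textureMap} is a bare mask.
#' @return list with \code{stego} (\linkS4class{GrayImage}) and \code{record}
#'   (\linkS4class{PEERecord}).
#' @export
embedStream <- function(image, textureMap, stream, errorRange = c(-2L, 2L),
                        keyRect = NULL, blockSize = 8L) {
  stopifnot(is(image, "GrayImage"))
  if (is(textureMap, "TextureMap")) {
    mask <- textureMap@embeddable
    keyRect <- textureMap@keyRect
    blockSize <- textureMap@blockSize
  } else {
    mask <- textureMap
    keyRect <- if (is.null(keyRect)) integer(0) else as.integer(keyRect)
  }
  stream <- as.integer(stream)
  if (length(stream) && !all(stream %in% c(0L, 1L)))
    .rc_error("roicrypt_format_error", "stream must contain only bits 0/1")
  p <- as.integer(errorRange[1L]); q <- as.integer(errorRange[2L])
  stopifnot(p <= 0L, q >= 0L)
  res <- .pee_embed(image@pixels, mask, as.integer(blockSize), keyRect, p, q, stream)
  if (res$shortfall)
    .rc_error("roicrypt_capacity_error",
              "payload of %d bits exceeds the available capacity of %d bits at range [%d, %d]",
              length(stream), res$used, p, q)
  record <- new("PEERecord", p = p, q = q,
                payloadBits = length(stream), nEvenBits = res$nEven,
                locationMap = res$skip, tileMask = mask,
                blockSize = as.integer(blockSize), keyRect = keyRect,
                imageDim = dim(image@pixels))
  list(stego = grayImage(res$px), record = record)
}

# -- extraction -----------------------------------------------------------

.pee_extract_pass <- function(px, H, targets, p, q, nBits, skipSet, fullLayer) {
  n <- length(targets)
  if (n == 0L || (!fullLayer && nBits == 0L))
    return(list(px = px, bits = integer(0)))
  v <- px[targets]
  s <- px[targets - 1L] + px[targets + 1L] + px[targets - H] + px[targets + H]
  D <- (s - 4L * v) %/% 4L
  skip <- skipSet[targets]
  consume <- D >= 2L * p & D <= 2L * q + 1L & !skip
  cum <- cumsum(consume)
  if (fullLayer) {
    if (cum[n] != nBits)
      .rc_error("roicrypt_integrity_error",
                "side information inconsistent: layer holds %d bits, record says %d",
                cum[n], nBits)
    stopPos <- n
  } else {
    if (cum[n] < nBits)
      .rc_error("roicrypt_integrity_error",
                "side information inconsistent: layer holds %d bits, record says %d",
                cum[n], nBits)
    stopPos <- match(nBits, cum)
  }
  act <- seq_len(stopPos)
  delta <- integer(n)
  delta[!skip & D > 2L * q + 1L] <- q + 1L
  delta[!skip & D < 2L * p] <- p
  cIdx <- which(consume)[seq_len(nBits)]
  delta[cIdx] <- D[cIdx] - D[cIdx] %/% 2L   # v = v' + (D - d)
  px[targets[act]] <- v[act] + delta[act]
  list(px = px, bits = D[cIdx] %% 2L)
}

#' Extract an embedded bitstream and restore the carrier
#'
#' Replays the embedding in reverse layer order (odd checkerboard layer
#' first, then even) and returns the payload bits together with the restored
#' carrier, which is pixel-identical to the original image.
#'
#' @param stego the stego \linkS4class{GrayImage}.
#' @param record the \linkS4class{PEERecord} produced at embedding time.
#' @return list with \code{bits} (integer vector of length
#'   \code{payloadBits(record)}) and \code{restored} (\linkS4class{GrayImage}).
#' @export
extractStream <- function(stego, record) {
  stopifnot(is(stego, "GrayImage"), is(record, "PEERecord"))
  px <- stego@pixels
  if (!identical(dim(px), record@imageDim))
    .rc_error("roicrypt_integrity_error",
              "image dimensions do not match the embedding record")
  H <- nrow(px)
  skipSet <- logical(length(px))
  skipSet[record@locationMap] <- TRUE
  nOdd <- record@payloadBits - record@nEvenBits
  tOdd <- .pee_targets(dim(px), record@tileMask, record@blockSize,
                       record@keyRect, 1L)
  resO <- .pee_extract_pass(px, H, tOdd, record@p, record@q, nOdd, skipSet,
                            fullLayer = FALSE)
  px <- resO$px
  tEven <- .pee_targets(dim(px), record@tileMask, record@blockSize,
                        record@keyRect, 0L)
  resE <- .pee_extract_pass(px, H, tEven, record@p, record@q,
                            record@nEvenBits, skipSet,
                            fullLayer = nOdd > 0L)
  list(bits = as.integer(c(resE$bits, resO$bits)),
       restored = grayImage(resE$px))
}

#' Embedding capacity of a texture map
#'
#' The number of payload bits the embeddable area can carry at the given
#' error range, measured by a dry-run embedding of an all-zero stream (the
#' second checkerboard layer is predicted from the modified first layer, so
#' capacity is a property of the full two-pass procedure, not a static pixel
#' count). Non-decreasing as [p, q] widens.
#'
#' @inheritParams embedStream
#' @return integer capacity in bits.
#' @export
peeCapacity <- function(image, textureMap, errorRange = c(-2L, 2L),
                        keyRect = NULL, blockSize = 8L) {
  stopifnot(is(image, "GrayImage"))
  if (is(textureMap, "TextureMap")) {
    mask <- textureMap@embeddable
    keyRect <- textureMap@keyRect
    blockSize <- textureMap@blockSize
  } else {
    mask <- textureMap
    keyRect <- if (is.null(keyRect)) integer(0) else as.integer(keyRect)
  }
  p <- as.integer(errorRange[1L]); q <- as.integer(errorRange[2L])
  nTot <- length(.pee_targets(dim(image@pixels), mask, blockSize, keyRect, 0L)) +
          length(.pee_targets(dim(image@pixels), mask, blockSize, keyRect, 1L))
  if (nTot == 0L) return(0L)
  res <- .pee_embed(image@pixels, mask, as.integer(blockSize), keyRect, p, q,
                    integer(nTot + 1L))   # more bits than pixels: counts capacity
  res$used
}

# bits <-> pixel helpers (least-significant-bit-first within each byte,
# column-major pixel order; the internal serialization convention).
.pixels_to_bits <- function(px) {
  as.integer(rawToBits(as.raw(as.vector(px))))
}

.bits_to_pixels <- function(bits, nr, nc) {
  stopifnot(length(bits) == nr * nc * 8L)
  matrix(as.integer(packBits(as.integer(bits), type = "raw")), nr, nc)
}
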