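# Full encryption / decryption orchestration.
#
# Encryption: select the key region by maximal Cv -> serialize its 25,600
# pixels to a 204,800-bit stream -> classify 8x8 blocks at threshold T ->
# embed the stream by PEE into the texture area -> Arnold-scramble every
# post-embedding tile with MSE > 0 -> replace the key region with the code
# block carrying cleartext metadata and RSA-protected parameters.
# Decryption inverts the stages in reverse order and is bit-exact.
#
# When {MSE > T} cannot hold the payload, the encoder adds further tiles in
# descending-MSE order (equivalently: lowers the effective threshold) until
# it fits; if even the full grid is insufficient at the requested error
# range, the range is widened symmetrically up to [-20, 20] before giving up.

# estimated extra capacity per tile: in-range prediction errors counted on
# the unmodified image (ignores layer interaction; used only to size the
# descending-MSE top-up before reattempting a real embedding)
.tile_cap_estimate <- function(px, b, keyRect, p, q) {
  H <- nrow(px); W <- ncol(px)
  valid <- matrix(FALSE, H, W)
  valid[2:(H - 1L), 2:(W - 1L)] <- TRUE
  if (length(keyRect) == 3L) {
    r0 <- keyRect[1L]; c0 <- keyRect[2L]; ks <- keyRect[3L]
    valid[max(1L, r0 - 1L):min(H, r0 + ks), max(1L, c0):min(W, c0 + ks - 1L)] <- FALSE
    valid[max(1L, r0):min(H, r0 + ks - 1L), max(1L, c0 - 1L):min(W, c0 + ks)] <- FALSE
  }
  dmat <- matrix(0L, H, W)
  i <- 2:(H - 1L); j <- 2:(W - 1L)
  s <- px[i - 1L, j] + px[i + 1L, j] + px[i, j - 1L] + px[i, j + 1L]
  dmat[i, j] <- (s - 4L * px[i, j]) %/% 4L
  ok <- valid & dmat >= p & dmat <= q
  ntr <- H %/% b; ntc <- W %/% b
  core <- ok[seq_len(ntr * b), seq_len(ntc * b)]
  t(rowsum(t(rowsum(core + 0L, rep(seq_len(ntr), each = b))),
           rep(seq_len(ntc), each = b)))
}

.widened_ranges <- function(errorRange) {
  p <- as.integer(errorRange[1L]); q <- as.integer(errorRange[2L])
  w0 <- max(-p, q)
  out <- list(c(p, q))
  if (w0 < 20L)
    for (w in (w0 + 1L):20L) out[[length(out) + 1L]] <- c(-w, w)
  out
}

#' Encrypt a medical image
#'
#' Runs the full protection pipeline and returns the encrypted image (same
#' dimensions as the input) together with an echo of every parameter used.
#' The pipeline is deterministic apart from the RSA key wrap inside the code
#' block.
#'
#' @param image a \linkS4class{GrayImage}, at least 160 x 160.
#' @param info a \linkS4class{BasicInfo} metadata record.
#' @param pubkey an openssl RSA public key.
#' @param threshold texture threshold T (default 5; the study sweeps 5..50).
#' @param errorRange integer(2) PEE error selection range (default c(-2, 2)).
#' @param arnoldK Arnold iteration count (default 4, the "8 x 8 4" setting).
#' @param keyTile optional manual key-region anchor (clinician override);
#'   NULL selects automatically by maximal coefficient of variation.
#' @param keySize key-region side (default 160).
#' @return an \linkS4class{EncryptionResult}.
#' @export
encryptImage <- function(image, info, pubkey, threshold = 5,
                         errorRange = c(-2L, 2L), arnoldK = 4L,
                         keyTile = NULL, keySize = 160L) {
  stopifnot(is(image, "GrayImage"), is(info, "BasicInfo"))
  keySize <- as.integer(keySize)
  d <- dim(image@pixels)
  if (min(d) < keySize)
    .rc_error("roicrypt_bounds_error",
              "image %d x %d is smaller than the %d x %d key region",
              d[1L], d[2L], keySize, keySize)
  stats <- if (is.null(keyTile)) selectKeyRegion(image, keySize)
           else overrideKeyRegion(image, keyTile, keySize)
  kt <- stats@tile
  keyRect <- c(kt, keySize)
  bits <- .pixels_to_bits(extractBlock(image, kt, keySize)@pixels)
  tm <- classifyBlocks(image, threshold, keyRect)
  ov <- .key_overlap_mask(nrow(tm@mse), ncol(tm@mse), tm@blockSize, keyRect)

  res <- NULL; mask <- NULL; rng <- NULL
  for (rng in .widened_ranges(errorRange)) {
    mask <- tm@embeddable
    res <- .pee_embed(image@pixels, mask, tm@blockSize, keyRect,
                      rng[1L], rng[2L], bits)
    if (!res$shortfall) break
    # top-up: lower the effective threshold by adding tiles in descending
    # MSE order until the payload fits
    est <- .tile_cap_estimate(image@pixels, tm@blockSize, keyRect,
                              rng[1L], rng[2L])
    rest <- which(!mask & !ov)
    rest <- rest[order(-tm@mse[rest], rest)]
    while (res$shortfall && length(rest) > 0L) {
      cumEst <- cumsum(est[rest])
      deficit <- length(bits) - res$used
      takeN <- which(cumEst >= 1.05 * deficit + 64)[1L]
      if (is.na(takeN)) takeN <- length(rest)
      mask[rest[seq_len(takeN)]] <- TRUE
      rest <- rest[-seq_len(takeN)]
      res <- .pee_embed(image@pixels, mask, tm@blockSize, keyRect,
                        rng[1L], rng[2L], bits)
    }
    if (!res$shortfall) break
  }
  if (res$shortfall)
    .rc_error("roicrypt_capacity_error",
              "key region needs %d bits but the image offers at most %d even at range [-20, 20]",
              length(bits), res$used)

  record <- new("PEERecord", p = rng[1L], q = rng[2L],
                payloadBits = length(bits), nEvenBits = res$nEven,
                locationMap = res$skip, tileMask = mask,
                blockSize = tm@blockSize, keyRect = keyRect, imageDim = d)
  stego <- grayImage(res$px)
  # scramble set: evaluated on the post-embedding image so encoder and
  # decoder agree; carried in the protected payload
  scrMask <- classifyBlocks(stego, 0, keyRect)@scramble
  scrambled <- scrambleRegion(stego, scrMask, arnoldK)
  params <- protectedParams(kt, keySize, threshold, arnoldK, record, scrMask)
  payload <- codePayload(info, encryptParams(params, pubkey), kt)
  out <- writeBlock(scrambled, kt, renderCodeBlock(payload, keySize))
  new("EncryptionResult", image = out, qrTile = kt, keySize = keySize,
      threshold = as.numeric(threshold), errorRange = as.integer(rng),
      arnoldK = as.integer(arnoldK), record = record, scrambleMask = scrMask,
      payload = payload)
}

#' Decrypt a protected image
#'
#' Locates and decodes the code block, unwraps the protected parameters with
#' the private key, inverts the Arnold scrambling, extracts the embedded
#' bitstream while restoring every carrier pixel, reassembles the 160 x 160
#' key region from the extracted bits, and returns the bit-exact original
#' image. A wrong key fails before any image reconstruction; a tampered
#' code block fails with a decode error.
#'
#' @param encrypted the protected \linkS4class{GrayImage} (or an
#'   \linkS4class{EncryptionResult}, whose image slot is used).
#' @param key the openssl RSA private key matching the encryption public key.
#' @param codeTile optional known anchor of the code block; NULL scans.
#' @param keySize code-block side (default 160).
#' @return the restored \linkS4class{GrayImage}.
#' @export
decryptImage <- function(encrypted, key, codeTile = NULL, keySize = 160L) {
  if (is(encrypted, "EncryptionResult")) encrypted <- encrypted@image
  stopifnot(is(encrypted, "GrayImage"))
  loc <- if (is.null(codeTile)) {
    locateCodeBlock(encrypted, keySize)
  } else {
    list(tile = as.integer(codeTile),
         payload = decodeCodeBlock(extractBlock(encrypted, codeTile, keySize)))
  }
  pp <- decryptParams(loc$payload@ciphertext, key)
  unscr <- unscrambleRegion(encrypted, pp@scrambleMask, pp@arnoldK)
  ex <- extractStream(unscr, pp@record)
  nKeyBits <- as.integer(pp@keySize)^2 * 8L
  if (length(ex$bits) < nKeyBits)
    .rc_error("roicrypt_integrity_error",
              "extracted stream shorter than the key region payload")
  keyBlock <- grayImage(.bits_to_pixels(ex$bits[seq_len(nKeyBits)],
                                        pp@keySize, pp@keySize))
  writeBlock(ex$restored, pp@keyTile, keyBlock)
}

#' Read the cleartext metadata without any key
#'
#' @param image the protected \linkS4class{GrayImage}.
#' @param keySize code-block side (default 160).
#' @return a \linkS4class{BasicInfo}.
#' @export
inspectCodeBlock <- function(image, keySize = 160L) {
  locateCodeBlock(image, keySize)$payload@basic
}

#' Simulate an unauthorized key-region reconstruction
#'
#' Models an attacker who reads the raw PEE bitstream from the protected
#' image as transmitted -- without the private key, hence without inverting
#' the Arnold scrambling -- and reassembles a 160 x 160 block from those
#' bits. Because the texture tiles are still scrambled, the recovered bits
#' are noise and the block bears no structural relation to the true key
#' region (SSIM below 0.1 on average).
#'
#' @param result an \linkS4class{EncryptionResult} (stands in for the side
#'   information an attacker might have exfiltrated; the private key is the
#'   only thing assumed secret).
#' @return a \linkS4class{GrayImage} of the attacker's reconstruction.
#' @export
unauthorizedReconstruction <- function(result) {
  stopifnot(is(result, "EncryptionResult"))
  px <- result@image@pixels
  rec <- result@record
  H <- nrow(px)
  skipSet <- logical(length(px))
  skipSet[rec@locationMap] <- TRUE
  bits <- list()
  for (parity in c(0L, 1L)) {   # assembly order: even-layer bits then odd
    tg <- .pee_targets(dim(px), rec@tileMask, rec@blockSize, rec@keyRect, parity)
    if (length(tg) == 0L) { bits[[parity + 1L]] <- integer(0); next }
    v <- px[tg]
    s <- px[tg - 1L] + px[tg + 1L] + px[tg - H] + px[tg + H]
    D <- (s - 4L * v) %/% 4L
    keep <- D >= 2L * rec@p & D <= 2L * rec@q + 1L & !skipSet[tg]
    bits[[parity + 1L]] <- D[keep] %% 2L
  }
  raw <- c(bits[[1L]], bits[[2L]])
  n <- result@keySize^2 * 8L
  raw <- c(raw, integer(max(0L, n - length(raw))))[seq_len(n)]
  grayImage(.bits_to_pixels(raw, result@keySize, result@keySize))
}

#' Sweep the texture threshold
#'
#' Encrypts the image at each threshold and reports the PSNR and SSIM of the
#' encrypted image against the original. As T grows, fewer blocks are
#' embedded and the visual quality of the protected image improves; once T
#' exceeds the largest usable block MSE the embedded set is driven purely by
#' capacity and the reports plateau.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param info a \linkS4class{BasicInfo}.
#' @param pubkey an openssl RSA public key.
#' @param thresholds ascending thresholds (default 5, 10, ..., 50).
#' @param ... further arguments passed to \code{\link{encryptImage}}.
#' @return data.frame with columns threshold, psnr, ssim.
#' @export
thresholdSweep <- function(image, info, pubkey,
                           thresholds = seq(5, 50, by = 5), ...) {
  stopifnot(!is.unsorted(thresholds))
  rows <- lapply(thresholds, function(T) {
    enc <- encryptImage(image, info, pubkey, threshold = T, ...)
    q <- imageQuality(image, enc@image)
    data.frame(threshold = T, psnr = q$psnr, ssim = q$ssim)
  })
  do.call(rbind, rows)
}
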