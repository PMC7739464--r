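# The code block that replaces the key region: cleartext patient metadata
# plus RSA-protected algorithm parameters, rendered as a 160 x 160 binary
# matrix code.
#
# The symbol layout is a quiet 4-pixel white border, a 2-pixel black frame,
# and a data field of (size - 12)^2 modules at one pixel per module. The
# data field carries, column-major and LSB-first per byte: a 4-byte magic,
# a 2-byte body length, an 8-byte SHA-256 truncation of the body, the body
# itself, then deterministic hash-chain padding. Any bit damage to header or
# body is caught by the checksum, which is what signals "illegally
# destroyed" content to a reader.

.CB_MAGIC <- charToRaw("RC01")
.CB_QUIET <- 4L
.CB_FRAME <- 2L

basicInfoFields <- function() {
  c("hospital", "department", "doctorNumber", "patientNumber",
    "shootingTime", "contactNumber", "imageType")
}

.basic_labels <- c(
  hospital = "Hospital", department = "Department",
  doctorNumber = "Doctor number", patientNumber = "Patient number",
  shootingTime = "Shooting time", contactNumber = "Contact number",
  imageType = "Image type")

#' Construct a BasicInfo metadata record
#'
#' @param hospital,department,doctorNumber,patientNumber,shootingTime,contactNumber,imageType
#'   single-line character fields; empty strings are allowed.
#' @return a \linkS4class{BasicInfo}.
#' @examples
#' basicInfoRecord(hospital = "union hospital", imageType = "brain CT")
#' @export
basicInfoRecord <- function(hospital = "", department = "", doctorNumber = "",
                            patientNumber = "", shootingTime = "",
                            contactNumber = "", imageType = "") {
  new("BasicInfo", hospital = hospital, department = department,
      doctorNumber = doctorNumber, patientNumber = patientNumber,
      shootingTime = shootingTime, contactNumber = contactNumber,
      imageType = imageType)
}

#' Serialize / parse BasicInfo
#'
#' Byte-stable text form: UTF-8 "Label: value" lines in fixed field order.
#'
#' @param info a \linkS4class{BasicInfo}.
#' @return \code{serializeBasicInfo}: a single string;
#'   \code{parseBasicInfo}: a \linkS4class{BasicInfo}.
#' @export
serializeBasicInfo <- function(info) {
  stopifnot(is(info, "BasicInfo"))
  paste(sprintf("%s: %s", .basic_labels[basicInfoFields()],
                vapply(basicInfoFields(), function(f) slot(info, f), "")),
        collapse = "\n")
}

#' @rdname serializeBasicInfo
#' @param text output of \code{serializeBasicInfo}.
#' @export
parseBasicInfo <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (length(lines) != length(basicInfoFields()))
    .rc_error("roicrypt_decode_error", "malformed metadata record")
  vals <- sub("^[^:]*: ?", "", lines)
  labs <- sub(":.*$", "", lines)
  if (!identical(labs, unname(.basic_labels[basicInfoFields()])))
    .rc_error("roicrypt_decode_error", "malformed metadata record")
  do.call(basicInfoRecord, as.list(stats::setNames(vals, basicInfoFields())))
}

# -- ProtectedParams binary serialization ---------------------------------

.wb <- function(con, x, size) writeBin(as.integer(x), con, size = size, endian = "little")
.rb <- function(con, n, size, signed = TRUE)
  readBin(con, "integer", n = n, size = size, signed = signed, endian = "little")

.pack_mask <- function(m) {
  bits <- as.logical(m)
  pad <- (-length(bits)) %% 8L
  packBits(c(bits, rep(FALSE, pad)), type = "raw")
}

.unpack_mask <- function(raw, ntr, ntc) {
  matrix(as.logical(rawToBits(raw))[seq_len(ntr * ntc)], ntr, ntc)
}

#' Bundle the decryption parameters
#'
#' @param keyTile integer(2) key-region anchor.
#' @param keySize key-region side (160 canonical).
#' @param threshold texture threshold T used by the encoder.
#' @param arnoldK Arnold iteration count.
#' @param record the \linkS4class{PEERecord} of the embedding.
#' @param scrambleMask logical tile matrix of scrambled tiles.
#' @return a \linkS4class{ProtectedParams}; its \code{arnoldText} is the
#'   human-readable "NxN k" form, e.g. "8 x 8 4".
#' @export
protectedParams <- function(keyTile, keySize, threshold, arnoldK, record,
                            scrambleMask) {
  new("ProtectedParams",
      arnoldText = sprintf("%d x %d %d", record@blockSize, record@blockSize,
                           as.integer(arnoldK)),
      keyTile = as.integer(keyTile), keySize = as.integer(keySize),
      threshold = as.numeric(threshold), arnoldK = as.integer(arnoldK),
      record = record, scrambleMask = scrambleMask)
}

.serialize_params <- function(pp) {
  stopifnot(is(pp, "ProtectedParams"))
  rec <- pp@record
  if (!identical(dim(rec@tileMask), dim(pp@scrambleMask)))
    .rc_error("roicrypt_format_error", "tile and scramble masks must share a grid")
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  .wb(con, 1L, 1L)                       # version
  .wb(con, pp@keyTile, 2L)
  .wb(con, pp@keySize, 2L)
  writeBin(pp@threshold, con, endian = "little")
  .wb(con, pp@arnoldK, 2L)
  at <- charToRaw(pp@arnoldText)
  .wb(con, length(at), 1L); writeBin(at, con)
  .wb(con, c(rec@p, rec@q), 1L)
  .wb(con, c(rec@payloadBits, rec@nEvenBits), 4L)
  .wb(con, rec@imageDim, 2L)
  .wb(con, rec@blockSize, 2L)
  .wb(con, length(rec@keyRect), 1L)
  if (length(rec@keyRect)) .wb(con, rec@keyRect, 2L)
  .wb(con, dim(rec@tileMask), 2L)
  writeBin(.pack_mask(rec@tileMask), con)
  writeBin(.pack_mask(pp@scrambleMask), con)
  .wb(con, length(rec@locationMap), 4L)
  if (length(rec@locationMap)) .wb(con, rec@locationMap, 4L)
  rawConnectionValue(con)
}

.parse_params <- function(bytes) {
  con <- rawConnection(bytes, "rb")
  on.exit(close(con))
  ver <- .rb(con, 1L, 1L)
  if (!identical(ver, 1L))
    .rc_error("roicrypt_decode_error", "unknown parameter serialization version")
  keyTile <- .rb(con, 2L, 2L)
  keySize <- .rb(con, 1L, 2L)
  threshold <- readBin(con, "double", endian = "little")
  arnoldK <- .rb(con, 1L, 2L)
  atLen <- .rb(con, 1L, 1L)
  arnoldText <- rawToChar(readBin(con, "raw", atLen))
  pq <- .rb(con, 2L, 1L)
  pb <- .rb(con, 2L, 4L)
  imageDim <- .rb(con, 2L, 2L)
  bsz <- .rb(con, 1L, 2L)
  krLen <- .rb(con, 1L, 1L)
  keyRect <- if (krLen > 0L) .rb(con, krLen, 2L) else integer(0)
  nt <- .rb(con, 2L, 2L)
  nBytes <- as.integer(ceiling(nt[1L] * nt[2L] / 8))
  tileMask <- .unpack_mask(readBin(con, "raw", nBytes), nt[1L], nt[2L])
  scrMask <- .unpack_mask(readBin(con, "raw", nBytes), nt[1L], nt[2L])
  nLoc <- .rb(con, 1L, 4L)
  locMap <- if (nLoc > 0L) .rb(con, nLoc, 4L) else integer(0)
  rec <- new("PEERecord", p = pq[1L], q = pq[2L], payloadBits = pb[1L],
             nEvenBits = pb[2L], locationMap = locMap, tileMask = tileMask,
             blockSize = bsz, keyRect = keyRect, imageDim = imageDim)
  new("ProtectedParams", arnoldText = arnoldText, keyTile = keyTile,
      keySize = keySize, threshold = threshold, arnoldK = arnoldK,
      record = rec, scrambleMask = scrMask)
}

# -- hybrid encryption ----------------------------------------------------

#' Generate an RSA key pair
#'
#' Convenience wrapper returning the private key and the matching public key.
#'
#' @param bits modulus size (default 2048).
#' @return list with openssl key objects \code{key} (private) and
#'   \code{pubkey}.
#' @export
rsaKeyPair <- function(bits = 2048L) {
  key <- openssl::rsa_keygen(bits)
  list(key = key, pubkey = as.list(key)$pubkey)
}

#' Encrypt the protected parameters
#'
#' Hybrid scheme with explicit authentication: the serialized parameters are
#' encrypted with AES-256-CTR under a content key and sealed encrypt-then-MAC
#' with HMAC-SHA256 (encryption and MAC keys are derived separately from the
#' content key); the content key is RSA-wrapped with the public key. The
#' content key and nonce are derived by hashing the serialized parameters,
#' so identical parameter bundles produce identical symmetric ciphertext
#' (convergent encryption) and the pipeline output is reproducible; only the
#' RSA wrap is randomized. A wrong private key or a tampered ciphertext
#' fails the MAC check and no plaintext is emitted.
#'
#' @param params a \linkS4class{ProtectedParams}.
#' @param pubkey an openssl RSA public key.
#' @return base64 ciphertext string.
#' @export
encryptParams <- function(params, pubkey) {
  pt <- .serialize_params(params)
  cek <- as.raw(openssl::sha256(c(pt, charToRaw("roicrypt/content-key"))))
  encKey <- openssl::sha256(charToRaw("enc"), key = cek)
  macKey <- openssl::sha256(charToRaw("mac"), key = cek)
  iv <- as.raw(openssl::sha256(c(pt, charToRaw("roicrypt/nonce"))))[1:16]
  ct <- openssl::aes_ctr_encrypt(pt, key = encKey, iv = iv)
  mac <- as.raw(openssl::sha256(c(iv, as.raw(ct)), key = macKey))
  wrapped <- openssl::rsa_encrypt(cek, pubkey)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  .wb(con, 1L, 1L)
  .wb(con, length(wrapped), 2L)
  writeBin(wrapped, con)
  writeBin(iv, con)
  writeBin(mac, con)
  .wb(con, length(ct), 4L)
  writeBin(as.raw(ct), con)
  openssl::base64_encode(rawConnectionValue(con))
}

#' Decrypt the protected parameters
#'
#' @param ciphertext base64 string from \code{\link{encryptParams}}.
#' @param key the matching openssl RSA private key.
#' @return a \linkS4class{ProtectedParams}.
#' @export
decryptParams <- function(ciphertext, key) {
  blob <- openssl::base64_decode(ciphertext)
  con <- rawConnection(blob, "rb")
  on.exit(close(con))
  if (!identical(.rb(con, 1L, 1L), 1L))
    .rc_error("roicrypt_decode_error", "unknown ciphertext framing version")
  wlen <- .rb(con, 1L, 2L)
  wrapped <- readBin(con, "raw", wlen)
  iv <- readBin(con, "raw", 16L)
  mac <- readBin(con, "raw", 32L)
  clen <- .rb(con, 1L, 4L)
  ct <- readBin(con, "raw", clen)
  cek <- tryCatch(as.raw(openssl::rsa_decrypt(wrapped, key)),
                  error = function(e)
                    .rc_error("roicrypt_key_error",
                              "private key cannot unwrap the content key"))
  keyOk <- length(cek) == 32L
  if (keyOk) {
    macKey <- openssl::sha256(charToRaw("mac"), key = cek)
    keyOk <- identical(as.raw(openssl::sha256(c(iv, ct), key = macKey)), mac)
  }
  if (!keyOk)
    .rc_error("roicrypt_key_error",
              "authenticated decryption failed (wrong key or tampered payload)")
  encKey <- openssl::sha256(charToRaw("enc"), key = cek)
  pt <- openssl::aes_ctr_decrypt(ct, key = encKey, iv = iv)
  .parse_params(pt)
}

# -- code block rendering -------------------------------------------------

#' Assemble a code-block payload
#'
#' @param basic a \linkS4class{BasicInfo}.
#' @param ciphertext base64 string from \code{\link{encryptParams}}.
#' @param keyTile integer(2) anchor of the key region (repeated in the clear;
#'   the block's position is visually apparent anyway).
#' @return a \linkS4class{CodePayload}.
#' @export
codePayload <- function(basic, ciphertext, keyTile) {
  new("CodePayload", basic = basic, ciphertext = ciphertext,
      keyTile = as.integer(keyTile))
}

.cb_data_side <- function(size) size - 2L * (.CB_QUIET + .CB_FRAME)

#' Render a payload as a matrix code block
#'
#' Produces a binarized (values 0/255) square block of the given size
#' containing the payload with a length header and SHA-256 checksum,
#' surrounded by a quiet border and a black frame. The canonical 160 x 160
#' block holds 25,600 pixels and up to 2,718 payload bytes at one pixel per
#' module.
#'
#' @param payload a \linkS4class{CodePayload}.
#' @param size block side in pixels (default 160).
#' @return a \linkS4class{GrayImage} with values in {0, 255}.
#' @export
renderCodeBlock <- function(payload, size = 160L) {
  stopifnot(is(payload, "CodePayload"))
  size <- as.integer(size)
  side <- .cb_data_side(size)
  capacity <- (side * side) %/% 8L - 14L
  basicRaw <- charToRaw(enc2utf8(serializeBasicInfo(payload@basic)))
  ctRaw <- openssl::base64_decode(payload@ciphertext)
  con <- rawConnection(raw(0), "wb")
  .wb(con, payload@keyTile, 2L)
  .wb(con, length(basicRaw), 2L)
  writeBin(basicRaw, con)
  .wb(con, length(ctRaw), 2L)
  writeBin(ctRaw, con)
  body <- rawConnectionValue(con)
  close(con)
  if (length(body) > capacity)
    .rc_error("roicrypt_capacity_error",
              "payload of %d bytes exceeds the %d-byte code block capacity; enlarge the block or trim the metadata",
              length(body), capacity)
  stream <- c(.CB_MAGIC, packBits(intToBits(length(body))[1:16], "raw"),
              openssl::sha256(body)[1:8], body)
  bits <- as.logical(rawToBits(stream))
  # deterministic hash-chain padding so the unused field looks like noise;
  # seeded from the stable payload parts only, so re-encrypting identical
  # parameters re-renders an (almost) identical block
  need <- side * side - length(bits)
  h <- openssl::sha256(c(.CB_MAGIC, basicRaw, as.raw(length(body) %% 256L)))
  pad <- raw(0)
  while (length(pad) * 8L < need) {
    pad <- c(pad, h)
    h <- openssl::sha256(h)
  }
  bits <- c(bits, as.logical(rawToBits(pad))[seq_len(need)])
  px <- matrix(255L, size, size)
  f0 <- .CB_QUIET + 1L; f1 <- .CB_QUIET + .CB_FRAME
  frame <- c(f0:f1, (size - f1 + 1L):(size - f0 + 1L))
  px[frame, f0:(size - f0 + 1L)] <- 0L
  px[f0:(size - f0 + 1L), frame] <- 0L
  d0 <- .CB_QUIET + .CB_FRAME + 1L
  px[d0:(d0 + side - 1L), d0:(d0 + side - 1L)] <-
    matrix(ifelse(bits, 0L, 255L), side, side)
  grayImage(px)
}

#' Decode a code block
#'
#' Binarizes the block at threshold 128, reads the data field, and verifies
#' the magic and checksum. Scrambled, overwritten or natural-image blocks
#' fail the verification, which is the signal that the protected image has
#' been illegally altered.
#'
#' @param block a square \linkS4class{GrayImage} (160 x 160 canonical).
#' @return a \linkS4class{CodePayload}.
#' @export
decodeCodeBlock <- function(block) {
  stopifnot(is(block, "GrayImage"))
  size <- nrow(block@pixels)
  if (size != ncol(block@pixels) || size < 2L * (.CB_QUIET + .CB_FRAME) + 16L)
    .rc_error("roicrypt_decode_error", "block too small to hold a code symbol")
  side <- .cb_data_side(size)
  d0 <- .CB_QUIET + .CB_FRAME + 1L
  bits <- block@pixels[d0:(d0 + side - 1L), d0:(d0 + side - 1L)] < 128L
  bytes <- packBits(as.vector(bits), type = "raw")
  if (!identical(bytes[1:4], .CB_MAGIC))
    .rc_error("roicrypt_decode_error", "no code symbol found (bad magic)")
  bodyLen <- as.integer(bytes[5L]) + 256L * as.integer(bytes[6L])
  capacity <- (side * side) %/% 8L - 14L
  if (is.na(bodyLen) || bodyLen < 8L || bodyLen > capacity)
    .rc_error("roicrypt_decode_error", "no code symbol found (implausible length)")
  body <- bytes[14L + seq_len(bodyLen)]
  if (!identical(as.raw(openssl::sha256(body)[1:8]), bytes[7:14]))
    .rc_error("roicrypt_decode_error",
              "checksum mismatch: code block damaged or image illegally altered")
  con <- rawConnection(body, "rb")
  on.exit(close(con))
  kt <- .rb(con, 2L, 2L)
  bl <- .rb(con, 1L, 2L)
  basic <- parseBasicInfo(rawToChar(readBin(con, "raw", bl)))
  cl <- .rb(con, 1L, 2L)
  ct <- readBin(con, "raw", cl)
  codePayload(basic, openssl::base64_encode(ct), kt)
}

#' Locate and decode the code block inside a protected image
#'
#' Tries the 160-grid anchors first (the automatic placement), then falls
#' back to an exhaustive scan for the symbol's magic bits, so manually
#' overridden off-grid placements are still found.
#'
#' @param image the protected \linkS4class{GrayImage}.
#' @param size code-block side (default 160).
#' @return list with \code{tile} (anchor found) and \code{payload}
#'   (\linkS4class{CodePayload}).
#' @export
locateCodeBlock <- function(image, size = 160L) {
  stopifnot(is(image, "GrayImage"))
  size <- as.integer(size)
  tryOne <- function(tile) {
    tryCatch(list(tile = tile,
                  payload = decodeCodeBlock(extractBlock(image, tile, size))),
             roicrypt_error = function(e) NULL)
  }
  d <- dim(image@pixels)
  if (min(d) >= size) {
    for (r in seq(1L, d[1L] - size + 1L, by = size))
      for (c in seq(1L, d[2L] - size + 1L, by = size)) {
        hit <- tryOne(c(r, c))
        if (!is.null(hit)) return(hit)
      }
    # exhaustive scan: match the 32 magic bits running down the first data column
    patt <- as.logical(rawToBits(.CB_MAGIC))
    A <- image@pixels < 128L
    off <- .CB_QUIET + .CB_FRAME
    nr <- d[1L] - size + 1L
    for (cc in seq_len(d[2L] - size + 1L)) {
      colv <- A[, cc + off]
      m <- rep(TRUE, nr)
      for (i in 0:31) {
        m <- m & (colv[seq_len(nr) + off + i] == patt[i + 1L])
        if (!any(m)) break
      }
      for (r in which(m)) {
        hit <- tryOne(c(r, cc))
        if (!is.null(hit)) return(hit)
      }
    }
  }
  .rc_error("roicrypt_decode_error",
            "no decodable code block found: image damaged or not protected by this scheme")
}
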