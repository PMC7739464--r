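#' @import methods
NULL

#' GrayImage: an 8-bit grayscale raster
#'
#' The carrier object used by every stage of the pipeline: a plain integer
#' matrix of pixel values in [0, 255]. Row 1 is the top row, column 1 the left
#' column; tiles and pixel positions are addressed 1-based as (row, col).
#'
#' @slot pixels integer matrix, values in [0, 255].
#' @exportClass GrayImage
setClass("GrayImage", representation(pixels = "matrix"))

setValidity("GrayImage", function(object) {
  px <- object@pixels
  if (!is.matrix(px) || !is.numeric(px))
    return("pixels must be a numeric matrix")
  if (nrow(px) < 1L || ncol(px) < 1L)
    return("image must have positive dimensions")
  if (anyNA(px))
    return("pixels must not contain NA")
  if (any(px != as.integer(px)))
    return("pixels must be integers")
  if (min(px) < 0 || max(px) > 255)
    return("pixel values must lie in [0, 255]")
  TRUE
})

#' BlockGrid: a non-overlapping square tiling of an image
#'
#' The maximal set of block-size tiles anchored at the top-left corner.
#' Trailing rows/columns that do not fill a tile are excluded from the grid
#' and recorded as the residual margin (e.g. 512 = 3 x 160 + 32).
#'
#' @slot blockSize side length of each tile, in pixels.
#' @slot imageDim integer(2), (height, width) of the tiled image.
#' @slot nTileRow,nTileCol number of tile rows / columns.
#' @slot residual integer(2), leftover (bottom, right) margin in pixels.
#' @exportClass BlockGrid
setClass("BlockGrid", representation(
  blockSize = "integer", imageDim = "integer",
  nTileRow = "integer", nTileCol = "integer", residual = "integer"))

setValidity("BlockGrid", function(object) {
  if (object@blockSize < 1L) return("blockSize must be positive")
  if (object@nTileRow < 1L || object@nTileCol < 1L)
    return("grid must contain at least one tile")
  if (any(object@residual < 0L) || any(object@residual >= object@blockSize))
    return("residual margin must be in [0, blockSize)")
  TRUE
})

#' KeyRegionStats: dispersion statistics of a candidate key region
#'
#' Holds the coefficient of variation C_v = sigma / mu of one tile, where
#' sigma is the population (1/N) standard deviation. The key region is the
#' 160x160 tile maximizing C_v.
#'
#' @slot tile integer(2), 1-based (row, col) anchor of the tile.
#' @slot size tile side length in pixels.
#' @slot mu mean pixel value.
#' @slot sigma population standard deviation.
#' @slot cv coefficient of variation (0 when mu is 0, by convention).
#' @slot nPixels number of pixels in the tile.
#' @exportClass KeyRegionStats
setClass("KeyRegionStats", representation(
  tile = "integer", size = "integer", mu = "numeric",
  sigma = "numeric", cv = "numeric", nPixels = "integer"))

setValidity("KeyRegionStats", function(object) {
  if (object@sigma < 0) return("sigma must be non-negative")
  if (object@cv < 0) return("cv must be non-negative")
  TRUE
})

#' TextureMap: smooth/texture classification of the block grid
#'
#' Per-tile mean squared error about the tile mean (equal to the tile's
#' population variance) over the full-image 8x8 grid, together with the
#' embeddable set {MSE > T}, the smooth set {MSE <= T}, and the scramble set
#' {MSE > 0}. Tiles overlapping the key region are excluded from both the
#' embeddable and the scramble set.
#'
#' @slot blockSize tile side (8 canonical).
#' @slot mse numeric matrix of per-tile MSE values (tile rows x tile cols).
#' @slot threshold the texture threshold T.
#' @slot embeddable logical matrix, tiles with MSE > T (minus key overlap).
#' @slot scramble logical matrix, tiles with MSE > 0 (minus key overlap).
#' @slot keyRect integer(3) (row, col, size) of the excluded key region,
#'   or integer(0) when no key region applies.
#' @exportClass TextureMap
setClass("TextureMap", representation(
  blockSize = "integer", mse = "matrix", threshold = "numeric",
  embeddable = "matrix", scramble = "matrix", keyRect = "integer"))

setValidity("TextureMap", function(object) {
  if (!identical(dim(object@mse), dim(object@embeddable)) ||
      !identical(dim(object@mse), dim(object@scramble)))
    return("mse, embeddable and scramble must share dimensions")
  if (object@threshold < 0) return("threshold must be non-negative")
  if (any(object@embeddable & !(object@mse > object@threshold)))
    return("embeddable tiles must satisfy MSE > threshold")
  TRUE
})

#' PEERecord: side information of a prediction-error-expansion embedding
#'
#' Everything the decoder needs to replay the embedding in reverse: the error
#' selection range [p, q], the number of payload bits (and how many were
#' placed in the even checkerboard layer), the overflow location map, and the
#' effective set of embeddable tiles. Serialized into the protected payload.
#'
#' @slot p,q error selection range, p <= 0 <= q.
#' @slot payloadBits total number of embedded bits.
#' @slot nEvenBits bits placed in the even ((row+col) even, 1-based) layer.
#' @slot locationMap sorted 1-based linear pixel indices skipped for
#'   overflow/underflow protection.
#' @slot tileMask logical matrix over the block grid: the effective
#'   embeddable set actually used.
#' @slot blockSize side of the grid tiles (8 canonical).
#' @slot keyRect integer(3) (row, col, size) of the excluded key region,
#'   or integer(0).
#' @slot imageDim integer(2) carrier dimensions.
#' @exportClass PEERecord
setClass("PEERecord", representation(
  p = "integer", q = "integer", payloadBits = "integer",
  nEvenBits = "integer", locationMap = "integer", tileMask = "matrix",
  blockSize = "integer", keyRect = "integer", imageDim = "integer"))

setValidity("PEERecord", function(object) {
  if (object@p > 0L || object@q < 0L) return("need p <= 0 <= q")
  if (object@payloadBits < 0L) return("payloadBits must be non-negative")
  if (object@nEvenBits < 0L || object@nEvenBits > object@payloadBits)
    return("nEvenBits must lie in [0, payloadBits]")
  TRUE
})

#' BasicInfo: cleartext patient/image metadata
#'
#' The seven-field record carried unencrypted in the code block so the image
#' remains retrievable without any key: hospital, department, doctor number,
#' patient number, shooting time, contact number, and image type. Fields may
#' be empty strings but must be single-line.
#'
#' @exportClass BasicInfo
setClass("BasicInfo", representation(
  hospital = "character", department = "character",
  doctorNumber = "character", patientNumber = "character",
  shootingTime = "character", contactNumber = "character",
  imageType = "character"))

setValidity("BasicInfo", function(object) {
  for (f in basicInfoFields()) {
    v <- slot(object, f)
    if (length(v) != 1L || is.na(v)) return(sprintf("field %s must be a single string", f))
    if (grepl("[\r\n]", v)) return(sprintf("field %s must not contain newlines", f))
  }
  TRUE
})

#' ProtectedParams: the secret parameter bundle
#'
#' The parameters an authorized party needs to invert every encryption stage:
#' the Arnold plaintext (e.g. "8 x 8 4"), the key-region placement, the
#' texture threshold, the scramble set, and the full PEE side information.
#' Travels RSA-protected inside the code block.
#'
#' @slot arnoldText human-readable Arnold parameters, "NxN k" form.
#' @slot keyTile integer(2) 1-based anchor of the replaced key region.
#' @slot keySize key-region side length (160 canonical).
#' @slot threshold texture threshold T used by the encoder.
#' @slot arnoldK number of Arnold iterations applied.
#' @slot record the \linkS4class{PEERecord} of the embedding.
#' @slot scrambleMask logical matrix over the block grid: scrambled tiles.
#' @exportClass ProtectedParams
setClass("ProtectedParams", representation(
  arnoldText = "character", keyTile = "integer", keySize = "integer",
  threshold = "numeric", arnoldK = "integer", record = "PEERecord",
  scrambleMask = "matrix"))

#' CodePayload: contents of the code block replacing the key region
#'
#' Cleartext \linkS4class{BasicInfo} plus the base64 ciphertext of the
#' \linkS4class{ProtectedParams}, with the key-region anchor repeated in the
#' clear (the block position is visually apparent in any case).
#'
#' @exportClass CodePayload
setClass("CodePayload", representation(
  basic = "BasicInfo", ciphertext = "character", keyTile = "integer"))

#' EncryptionResult: output of the full encryption pipeline
#'
#' The protected image (same dimensions as the input) together with an echo
#' of every parameter the encoder chose. The transmitted artifact is the
#' image alone; the remaining slots duplicate, in the clear, what an
#' authorized decoder recovers from the code block, and exist for auditing
#' and for simulating unauthorized access.
#'
#' @exportClass EncryptionResult
setClass("EncryptionResult", representation(
  image = "GrayImage", qrTile = "integer", keySize = "integer",
  threshold = "numeric", errorRange = "integer", arnoldK = "integer",
  record = "PEERecord", scrambleMask = "matrix", payload = "CodePayload"))
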