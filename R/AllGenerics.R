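# Generics, accessors and show methods. Slots are never reached into by user
# code; these accessors are the supported surface.

#' @export
setGeneric("pixelMatrix", function(x) standardGeneric("pixelMatrix"))

#' Pixel matrix of a GrayImage
#'
#' @param x a \linkS4class{GrayImage}.
#' @return integer matrix of pixel values in [0, 255].
#' @export
setMethod("pixelMatrix", "GrayImage", function(x) x@pixels)

#' @describeIn pixelMatrix image of an \linkS4class{EncryptionResult}.
#' @export
setMethod("pixelMatrix", "EncryptionResult", function(x) x@image@pixels)

#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' @export
setGeneric("blockSize", function(x) standardGeneric("blockSize"))
#' @export
setMethod("blockSize", "BlockGrid", function(x) x@blockSize)
#' @export
setMethod("blockSize", "TextureMap", function(x) x@blockSize)

#' @export
setGeneric("nTiles", function(x) standardGeneric("nTiles"))

#' Tile-grid dimensions
#' @param x a \linkS4class{BlockGrid} or \linkS4class{TextureMap}.
#' @return integer(2): tile rows, tile columns.
#' @export
setMethod("nTiles", "BlockGrid", function(x) c(x@nTileRow, x@nTileCol))
#' @export
setMethod("nTiles", "TextureMap", function(x) dim(x@mse))

#' @export
setGeneric("residualMargin", function(x) standardGeneric("residualMargin"))
#' @export
setMethod("residualMargin", "BlockGrid", function(x) x@residual)

#' @export
setGeneric("cvValue", function(x) standardGeneric("cvValue"))
#' @export
setMethod("cvValue", "KeyRegionStats", function(x) x@cv)

#' @export
setGeneric("keyTile", function(x) standardGeneric("keyTile"))
#' @export
setMethod("keyTile", "KeyRegionStats", function(x) x@tile)
#' @export
setMethod("keyTile", "EncryptionResult", function(x) x@qrTile)
#' @export
setMethod("keyTile", "CodePayload", function(x) x@keyTile)

#' @export
setGeneric("mseMatrix", function(x) standardGeneric("mseMatrix"))
#' @export
setMethod("mseMatrix", "TextureMap", function(x) x@mse)

#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))
#' @export
setMethod("threshold", "TextureMap", function(x) x@threshold)

#' @export
setGeneric("embeddableMask", function(x) standardGeneric("embeddableMask"))
#' @export
setMethod("embeddableMask", "TextureMap", function(x) x@embeddable)

#' @export
setGeneric("scrambleMask", function(x) standardGeneric("scrambleMask"))
#' @export
setMethod("scrambleMask", "TextureMap", function(x) x@scramble)
#' @export
setMethod("scrambleMask", "EncryptionResult", function(x) x@scrambleMask)

#' Embeddable tiles in ascending-MSE order
#'
#' Anchors of the embeddable tiles sorted by increasing MSE (ties broken by
#' row-major tile index), the order in which the encoder considers texture
#' blocks.
#'
#' @param x a \linkS4class{TextureMap}.
#' @return two-column integer matrix of 1-based tile (row, col) anchors.
#' @export
setGeneric("embeddableTiles", function(x) standardGeneric("embeddableTiles"))

#' @export
setMethod("embeddableTiles", "TextureMap", function(x) {
  nt <- dim(x@mse)
  idx <- which(x@embeddable)                     # column-major tile indices
  tr <- (idx - 1L) %% nt[1L] + 1L
  tc <- (idx - 1L) %/% nt[1L] + 1L
  rowMajor <- (tr - 1L) * nt[2L] + tc
  ord <- order(x@mse[idx], rowMajor)
  cbind(row = (tr[ord] - 1L) * x@blockSize + 1L,
        col = (tc[ord] - 1L) * x@blockSize + 1L)
})

#' @export
setGeneric("payloadBits", function(x) standardGeneric("payloadBits"))
#' @export
setMethod("payloadBits", "PEERecord", function(x) x@payloadBits)

#' @export
setGeneric("errorRange", function(x) standardGeneric("errorRange"))
#' @export
setMethod("errorRange", "PEERecord", function(x) c(x@p, x@q))
#' @export
setMethod("errorRange", "EncryptionResult", function(x) x@errorRange)

#' @export
setGeneric("locationMap", function(x) standardGeneric("locationMap"))
#' @export
setMethod("locationMap", "PEERecord", function(x) x@locationMap)

#' @export
setGeneric("basicInfo", function(x) standardGeneric("basicInfo"))
#' @export
setMethod("basicInfo", "CodePayload", function(x) x@basic)
#' @export
setMethod("basicInfo", "EncryptionResult", function(x) x@payload@basic)

#' @export
setGeneric("ciphertext", function(x) standardGeneric("ciphertext"))
#' @export
setMethod("ciphertext", "CodePayload", function(x) x@ciphertext)

# -- show methods --------------------------------------------------------

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GrayImage %d x %d, range [%d, %d]\n",
              d[1L], d[2L], min(object@pixels), max(object@pixels)))
})

setMethod("show", "BlockGrid", function(object) {
  cat(sprintf("BlockGrid: %d x %d tiles of %d px (residual margin %d bottom, %d right)\n",
              object@nTileRow, object@nTileCol, object@blockSize,
              object@residual[1L], object@residual[2L]))
})

setMethod("show", "KeyRegionStats", function(object) {
  cat(sprintf("KeyRegionStats: tile (%d, %d) size %d | mu %.3f sigma %.3f Cv %.4f\n",
              object@tile[1L], object@tile[2L], object@size,
              object@mu, object@sigma, object@cv))
})

setMethod("show", "TextureMap", function(object) {
  cat(sprintf("TextureMap: %d x %d tiles of %d px, T = %g\n",
              nrow(object@mse), ncol(object@mse), object@blockSize,
              object@threshold))
  cat(sprintf("  embeddable %d | smooth %d | scramble %d\n",
              sum(object@embeddable), sum(!object@embeddable),
              sum(object@scramble)))
})

setMethod("show", "PEERecord", function(object) {
  cat(sprintf("PEERecord: range [%d, %d], %d bits (%d even layer), %d overflow-skipped px, %d tiles\n",
              object@p, object@q, object@payloadBits, object@nEvenBits,
              length(object@locationMap), sum(object@tileMask)))
})

setMethod("show", "BasicInfo", function(object) {
  cat(serializeBasicInfo(object))
  cat("\n")
})

setMethod("show", "EncryptionResult", function(object) {
  d <- dim(object@image@pixels)
  cat(sprintf("EncryptionResult: %d x %d image, code block at (%d, %d) size %d\n",
              d[1L], d[2L], object@qrTile[1L], object@qrTile[2L], object@keySize))
  cat(sprintf("  T = %g, error range [%d, %d], Arnold k = %d, %d bits embedded\n",
              object@threshold, object@errorRange[1L], object@errorRange[2L],
              object@arnoldK, object@record@payloadBits))
})
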