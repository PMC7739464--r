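# Image reading/writing and the block-grid coordinate system.
#
# Conventions used throughout the package: pixel (1, 1) is the top-left
# corner; a tile is addressed by the 1-based (row, col) of its top-left pixel
# and covers rows r .. r+size-1 and columns c .. c+size-1.

.rc_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "roicrypt_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1L))))
}

#' Construct a GrayImage from a matrix
#'
#' @param pixels numeric matrix with integer values in [0, 255].
#' @return a \linkS4class{GrayImage}.
#' @examples
#' img <- grayImage(matrix(0:255, 16, 16))
#' dim(img)
#' @export
grayImage <- function(pixels) {
  px <- as.matrix(pixels)
  storage.mode(px) <- "integer"
  new("GrayImage", pixels = px)
}

#' Read an 8-bit grayscale image
#'
#' Supports PNG and PGM (binary P5 and ASCII P2, maxval <= 255). Color,
#' alpha-carrying and >8-bit inputs are rejected with a format error rather
#' than silently converted.
#'
#' @param path path to a .png, .pgm or .pnm file.
#' @return a \linkS4class{GrayImage}.
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path))
    .rc_error("roicrypt_format_error", "file not found: %s", path)
  magic <- readBin(path, "raw", n = 8L)
  if (length(magic) >= 8L &&
      identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))) {
    .read_png_gray(path)
  } else if (length(magic) >= 2L && magic[1L] == charToRaw("P") &&
             magic[2L] %in% c(charToRaw("2"), charToRaw("5"))) {
    .read_pgm(path)
  } else {
    .rc_error("roicrypt_format_error", "unsupported image format: %s", path)
  }
}

.read_png_gray <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L)
    .rc_error("roicrypt_format_error",
              "non-grayscale PNG (%d channels); only single-channel 8-bit input is accepted",
              dim(arr)[3L])
  px <- round(arr * 255)
  if (max(abs(arr * 255 - px)) > 1e-6)
    .rc_error("roicrypt_format_error",
              "PNG is not 8-bit; >8-bit depths are rejected, not converted")
  grayImage(px)
}

.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {   # next whitespace-delimited token, '#' comments skipped
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) .rc_error("roicrypt_format_error", "truncated PGM header")
      if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE)
        if (length(c2) == 0L || c2 == "\n") break } ; next }
      if (!grepl("[[:space:]]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  w <- as.integer(tok()); h <- as.integer(tok()); maxval <- as.integer(tok())
  if (is.na(w) || is.na(h) || w < 1L || h < 1L)
    .rc_error("roicrypt_format_error", "invalid PGM dimensions")
  if (is.na(maxval) || maxval > 255L)
    .rc_error("roicrypt_format_error",
              "PGM maxval %s exceeds 255; >8-bit input is rejected", maxval)
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    vals <- integer(0)
    while (length(vals) < w * h) {
      t <- tok()
      if (!nzchar(t)) .rc_error("roicrypt_format_error", "truncated PGM data")
      vals <- c(vals, as.integer(t))
    }
  }
  if (length(vals) < w * h)
    .rc_error("roicrypt_format_error", "truncated PGM data")
  grayImage(matrix(vals[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE))
}

#' Write an 8-bit grayscale image
#'
#' Bit-exact writers: an image written and re-read round-trips identically.
#' Format is chosen by extension (.png, or .pgm/.pnm for binary P5).
#'
#' @param image a \linkS4class{GrayImage}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGrayImage <- function(image, path) {
  stopifnot(is(image, "GrayImage"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image@pixels / 255, target = path)
  } else if (ext %in% c("pgm", "pnm")) {
    con <- file(path, "wb")
    on.exit(close(con))
    d <- dim(image@pixels)
    writeChar(sprintf("P5\n%d %d\n255\n", d[2L], d[1L]), con, eos = NULL)
    writeBin(as.raw(t(image@pixels)), con)
  } else {
    .rc_error("roicrypt_format_error", "unsupported output format: .%s", ext)
  }
  invisible(path)
}

#' Tile an image into a block grid
#'
#' Returns the maximal set of non-overlapping square tiles anchored at the
#' top-left corner. Trailing rows/columns that do not fill a tile are
#' excluded and reported as the residual margin: a 512x512 image tiled at 160
#' yields a 3x3 grid with a 32-pixel margin on the right and bottom.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param blockSize tile side in pixels; must not exceed either image side.
#' @return a \linkS4class{BlockGrid}.
#' @export
blockGrid <- function(image, blockSize) {
  stopifnot(is(image, "GrayImage"))
  blockSize <- as.integer(blockSize)
  d <- dim(image@pixels)
  if (blockSize > min(d))
    .rc_error("roicrypt_bounds_error",
              "blockSize %d exceeds image dimensions %d x %d", blockSize, d[1L], d[2L])
  new("BlockGrid", blockSize = blockSize, imageDim = d,
      nTileRow = d[1L] %/% blockSize, nTileCol = d[2L] %/% blockSize,
      residual = as.integer(d %% blockSize))
}

#' Tile anchors of a block grid
#'
#' @param grid a \linkS4class{BlockGrid}.
#' @return two-column integer matrix of 1-based (row, col) anchors in
#'   row-major tile order.
#' @export
gridTiles <- function(grid) {
  stopifnot(is(grid, "BlockGrid"))
  b <- grid@blockSize
  tr <- rep(seq_len(grid@nTileRow), each = grid@nTileCol)
  tc <- rep(seq_len(grid@nTileCol), times = grid@nTileRow)
  cbind(row = (tr - 1L) * b + 1L, col = (tc - 1L) * b + 1L)
}

.check_tile <- function(image, tile, size) {
  d <- dim(image@pixels)
  tile <- as.integer(tile)
  if (length(tile) != 2L || any(is.na(tile)) || any(tile < 1L) ||
      tile[1L] + size - 1L > d[1L] || tile[2L] + size - 1L > d[2L])
    .rc_error("roicrypt_bounds_error",
              "tile (%s) of size %d does not fit a %d x %d image",
              paste(tile, collapse = ", "), size, d[1L], d[2L])
  tile
}

#' Extract a square block from an image
#'
#' Any in-bounds placement is legal, including anchors that are not on a
#' block grid.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param tile integer(2), 1-based (row, col) anchor.
#' @param size block side in pixels.
#' @return a \linkS4class{GrayImage} copy of the block.
#' @export
extractBlock <- function(image, tile, size) {
  stopifnot(is(image, "GrayImage"))
  size <- as.integer(size)
  tile <- .check_tile(image, tile, size)
  grayImage(image@pixels[tile[1L]:(tile[1L] + size - 1L),
                         tile[2L]:(tile[2L] + size - 1L), drop = FALSE])
}

#' Replace a square block in an image
#'
#' Returns a new image; \code{writeBlock(img, tile, extractBlock(img, tile, size))}
#' is the identity.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param tile integer(2), 1-based (row, col) anchor.
#' @param block a \linkS4class{GrayImage} whose dimensions give the extent.
#' @return a new \linkS4class{GrayImage}.
#' @export
writeBlock <- function(image, tile, block) {
  stopifnot(is(image, "GrayImage"), is(block, "GrayImage"))
  d <- dim(block@pixels)
  if (d[1L] != d[2L])
    .rc_error("roicrypt_bounds_error", "block must be square")
  tile <- .check_tile(image, tile, d[1L])
  px <- image@pixels
  px[tile[1L]:(tile[1L] + d[1L] - 1L),
     tile[2L]:(tile[2L] + d[2L] - 1L)] <- block@pixels
  grayImage(px)
}
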