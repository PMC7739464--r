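# Image I/O and the block-grid coordinate system.

test_that("PGM files are read identically to their raw pixel content", {
  path <- withr::local_tempfile(fileext = ".pgm")
  writeBin(c(charToRaw("P5\n2 2\n255\n"), as.raw(c(0, 255, 128, 7))), path)
  img <- readGrayImage(path)
  expect_identical(pixelMatrix(img), matrix(c(0L, 128L, 255L, 7L), 2, 2))

  # ASCII P2 with a comment line
  p2 <- withr::local_tempfile(fileext = ".pgm")
  writeLines(c("P2", "# a comment", "3 2", "255", "1 2 3", "4 5 6"), p2)
  expect_identical(pixelMatrix(readGrayImage(p2)),
                   matrix(c(1L, 4L, 2L, 5L, 3L, 6L), 2, 3))
})

test_that("color and >8-bit inputs are rejected, not converted", {
  rgb <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(12), c(2, 2, 3)), rgb)
  expect_error(readGrayImage(rgb), class = "roicrypt_format_error")

  deep <- withr::local_tempfile(fileext = ".pgm")
  writeLines(c("P2", "1 1", "65535", "40000"), deep)
  expect_error(readGrayImage(deep), class = "roicrypt_format_error")

  expect_error(readGrayImage(tempfile()), class = "roicrypt_format_error")
})

test_that("write/read round trips are pixel-exact for PNG and PGM", {
  img <- generatePhantom(11, size = 256L, lesionTile = c(1L, 1L))
  for (ext in c(".png", ".pgm")) {
    path <- withr::local_tempfile(fileext = ext)
    writeGrayImage(img, path)
    expect_identical(pixelMatrix(readGrayImage(path)), pixelMatrix(img))
  }
})

test_that("block grids tile maximally with the residual margin recorded", {
  img512 <- grayImage(matrix(0L, 512, 512))
  g <- blockGrid(img512, 160)
  expect_identical(nTiles(g), c(3L, 3L))
  expect_identical(residualMargin(g), c(32L, 32L))
  expect_identical(nrow(gridTiles(g)), 9L)

  expect_identical(nTiles(blockGrid(img512, 8)), c(64L, 64L))
  expect_identical(residualMargin(blockGrid(img512, 8)), c(0L, 0L))
  expect_identical(nTiles(blockGrid(grayImage(matrix(7L, 160, 160)), 160)),
                   c(1L, 1L))
  expect_error(blockGrid(grayImage(matrix(0L, 10, 10)), 11),
               class = "roicrypt_bounds_error")

  set.seed(42)
  for (i in 1:10) {
    H <- sample(20:200, 1); W <- sample(20:200, 1); b <- sample(3:19, 1)
    g <- blockGrid(grayImage(matrix(0L, H, W)), b)
    expect_identical(as.integer(prod(nTiles(g))), (H %/% b) * (W %/% b))
  }
})

test_that("extract/write round trips are the identity for arbitrary tiles", {
  set.seed(7)
  img <- make_toy_carrier(7, size = 96L)
  for (i in 1:20) {
    tile <- c(sample(96 - 15, 1), sample(96 - 15, 1))
    blk <- extractBlock(img, tile, 16)
    expect_identical(pixelMatrix(writeBlock(img, tile, blk)), pixelMatrix(img))
  }

  # an off-grid but in-bounds far-corner extraction is legal
  big <- grayImage(matrix(0L, 512, 512))
  expect_silent(extractBlock(big, c(353, 353), 160))
  expect_error(extractBlock(big, c(354, 353), 160),
               class = "roicrypt_bounds_error")

  # overwriting a 160x160 tile changes at most 25,600 pixels
  out <- writeBlock(img <- generatePhantom(3), c(1, 1),
                    grayImage(matrix(0L, 160, 160)))
  expect_lte(sum(pixelMatrix(out) != pixelMatrix(img)), 25600L)
})
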