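# Coefficient of variation, block MSE, and smooth/texture classification.

test_that("coefficient of variation matches closed forms and a two-pass oracle", {
  s <- coefficientOfVariation(grayImage(matrix(77L, 12, 12)))
  expect_identical(s@sigma, 0)
  expect_identical(cvValue(s), 0)

  half <- grayImage(matrix(rep(c(0L, 255L), each = 8), 4, 4))
  s <- coefficientOfVariation(half)
  expect_equal(s@mu, 127.5)
  expect_equal(s@sigma, 127.5)
  expect_equal(cvValue(s), 1)

  # all-black blocks get Cv 0 by convention, never winning an argmax
  expect_identical(cvValue(coefficientOfVariation(grayImage(matrix(0L, 8, 8)))), 0)

  set.seed(101)
  blk <- grayImage(matrix(sample(0:255, 160 * 160, replace = TRUE), 160, 160))
  s <- coefficientOfVariation(blk)
  px <- pixelMatrix(blk)
  mu <- sum(px) / length(px)                      # independent two-pass oracle
  sg <- sqrt(sum((px - mu)^2) / length(px))
  expect_equal(s@mu, mu)
  expect_equal(s@sigma, sg)
  expect_equal(cvValue(s), sg / mu)
  expect_identical(s@nPixels, 25600L)
})

test_that("block MSE equals hand arithmetic and the Cv sigma squared", {
  expect_identical(blockMSE(grayImage(matrix(9L, 8, 8))), 0)
  expect_equal(blockMSE(grayImage(matrix(c(0L, 0L, 0L, 2L), 2, 2))), 0.75)
  set.seed(5)
  for (i in 1:10) {
    blk <- grayImage(matrix(sample(0:255, 64, replace = TRUE), 8, 8))
    expect_equal(blockMSE(blk), coefficientOfVariation(blk)@sigma^2)
  }
})

test_that("the key region is the maximal-Cv tile, ties broken row-major", {
  img <- generatePhantom(21, lesionTile = c(3L, 1L))
  expect_identical(keyTile(selectKeyRegion(img)), c(321L, 1L))

  expect_identical(keyTile(selectKeyRegion(grayImage(matrix(50L, 512, 512)))),
                   c(1L, 1L))

  # two identical lesion patches: the row-major-first one wins
  set.seed(8)
  patch <- matrix(sample(c(20L, 240L), 160 * 160, replace = TRUE), 160, 160)
  base <- matrix(100L, 512, 512)
  two <- base
  two[161:320, 1:160] <- patch      # tile (2, 1): row-major index 4
  two[161:320, 321:480] <- patch    # tile (2, 3): row-major index 6
  expect_identical(keyTile(selectKeyRegion(grayImage(two))), c(161L, 1L))

  # translation covariance: moving the patch moves the selection identically
  one <- base; one[1:160, 161:320] <- patch
  expect_identical(keyTile(selectKeyRegion(grayImage(one))), c(1L, 161L))

  expect_error(selectKeyRegion(grayImage(matrix(0L, 100, 100))),
               class = "roicrypt_bounds_error")
})

test_that("manual override bypasses the argmax at any in-bounds anchor", {
  img <- generatePhantom(4)
  s <- overrideKeyRegion(img, c(1L, 1L))
  expect_identical(keyTile(s), c(1L, 1L))
  expect_equal(cvValue(s),
               cvValue(coefficientOfVariation(extractBlock(img, c(1, 1), 160))))
  expect_silent(overrideKeyRegion(img, c(101L, 101L)))   # off-grid is legal
  expect_error(overrideKeyRegion(img, c(400L, 400L)),
               class = "roicrypt_bounds_error")
})

test_that("classification matches brute-force thresholding and is monotone in T", {
  flat <- classifyBlocks(grayImage(matrix(33L, 64, 64)), 5)
  expect_identical(sum(embeddableMask(flat)), 0L)
  expect_identical(sum(scrambleMask(flat)), 0L)

  img <- make_toy_carrier(31, size = 96L)
  ref <- naive_tile_var(pixelMatrix(img), 8L)
  for (T in c(0, 50, 300)) {
    tm <- classifyBlocks(img, T)
    expect_equal(mseMatrix(tm), ref)
    expect_identical(embeddableMask(tm), ref > T)
  }
  t0 <- embeddableMask(classifyBlocks(img, 0))
  t50 <- embeddableMask(classifyBlocks(img, 50))
  expect_true(all(t0[t50]))                       # embeddable(50) subset of (0)

  img2 <- generatePhantom(6)
  sizes <- sapply(seq(5, 50, 5), function(T)
    sum(embeddableMask(classifyBlocks(img2, T))))
  expect_true(all(diff(sizes) <= 0))              # non-increasing in T

  # tiles overlapping the key region are excluded from both sets
  tm <- classifyBlocks(img2, 5, keyRect = c(161L, 161L, 160L))
  expect_false(any(embeddableMask(tm)[21:40, 21:40]))
  expect_false(any(scrambleMask(tm)[21:40, 21:40]))
  expect_true(all(embeddableMask(tm) <= scrambleMask(tm)))  # embeddable within scramble

  ord <- embeddableTiles(tm)
  expect_true(!is.unsorted(apply(ord, 1, function(t)
    mseMatrix(tm)[(t[1] - 1) %/% 8 + 1, (t[2] - 1) %/% 8 + 1])))
})
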