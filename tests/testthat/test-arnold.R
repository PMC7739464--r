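# Arnold cat-map scrambling: bijectivity, periodicity, exact inversion, and
# the correlation-weakening property.

# brute-force period oracle: iterate the lattice permutation to identity
brute_period <- function(N) {
  pts <- expand.grid(x = 0:(N - 1), y = 0:(N - 1))
  x <- pts$x; y <- pts$y
  k <- 0L
  repeat {
    st <- arnoldStep(x, y, N)
    x <- st$x; y <- st$y
    k <- k + 1L
    if (all(x == pts$x) && all(y == pts$y)) return(k)
  }
}

test_that("the map fixes the origin and matches direct matrix arithmetic", {
  for (N in c(2, 8, 13)) {
    st <- arnoldStep(0, 0, N)
    expect_identical(c(st$x, st$y), c(0, 0))
  }
  st <- arnoldStep(1, 1, 8)
  expect_identical(c(st$x, st$y), c(2, 3))
})

test_that("the map is a bijection on every tested lattice", {
  for (N in 2:16) {
    g <- expand.grid(x = 0:(N - 1), y = 0:(N - 1))
    st <- arnoldStep(g$x, g$y, N)
    expect_identical(anyDuplicated(st$x * N + st$y), 0L)
  }
})

test_that("arnoldPeriod agrees with brute-force iteration to identity", {
  for (N in 2:16) expect_identical(arnoldPeriod(N), brute_period(N))
})

test_that("scramble/unscramble round trips are exact for every k", {
  set.seed(3)
  per <- arnoldPeriod(8L)
  blk <- grayImage(matrix(sample(0:255, 64, replace = TRUE), 8, 8))
  expect_identical(pixelMatrix(scrambleBlock(blk, 0)), pixelMatrix(blk))
  for (k in seq_len(per - 1L)) {
    scr <- scrambleBlock(blk, k)
    expect_identical(sort(pixelMatrix(scr)), sort(pixelMatrix(blk)))  # permutation
    expect_identical(pixelMatrix(unscrambleBlock(scr, k)), pixelMatrix(blk))
    # inverse-matrix unscrambling agrees with period - k forward steps
    expect_identical(pixelMatrix(scrambleBlock(scr, per - k)), pixelMatrix(blk))
  }
  # period(N) applications restore any block
  expect_identical(pixelMatrix(scrambleBlock(blk, per)), pixelMatrix(blk))
  expect_error(scrambleBlock(grayImage(matrix(0L, 4, 8)), 1),
               class = "roicrypt_bounds_error")
})

test_that("region scrambling touches only the scramble set and inverts exactly", {
  flat <- grayImage(matrix(44L, 64, 64))
  tm <- classifyBlocks(flat, 0)
  expect_identical(pixelMatrix(scrambleRegion(flat, tm)), pixelMatrix(flat))

  for (seed in 1:5) {
    img <- generatePhantom(seed, size = 256L, lesionTile = c(1L, 1L))
    tm <- classifyBlocks(img, 0, keyRect = c(1L, 1L, 160L))
    scr <- scrambleRegion(img, tm, k = 4)
    expect_identical(sort(pixelMatrix(scr)), sort(pixelMatrix(img)))  # histogram
    expect_identical(pixelMatrix(unscrambleRegion(scr, tm, k = 4)),
                     pixelMatrix(img))
    # untouched outside the scramble set: the key-region tiles
    expect_identical(pixelMatrix(scr)[1:160, 1:160],
                     pixelMatrix(img)[1:160, 1:160])
  }
})

test_that("scrambling weakens adjacent-pixel correlation on textured blocks", {
  lag1 <- function(px) {
    h <- cor(as.vector(px[, -ncol(px)]), as.vector(px[, -1]))
    v <- cor(as.vector(px[-nrow(px), ]), as.vector(px[-1, ]))
    mean(abs(c(h, v)))
  }
  drops <- sapply(1:20, function(seed) {
    set.seed(seed)
    base <- matrix(sample(60:90, 256, replace = TRUE), 16, 16)
    px <- t(apply(base, 1, cumsum) %% 140L) + 40L    # strong spatial correlation
    blk <- grayImage(matrix(as.integer(px), 16, 16))
    lag1(pixelMatrix(blk)) - lag1(pixelMatrix(scrambleBlock(blk, 3)))
  })
  expect_gt(mean(drops), 0.05)
})
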