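# Prediction-error expansion: elementary mappings, exhaustive invertibility,
# and full embed/extract round trips.

test_that("diamond prediction follows the printed formula with floor semantics", {
  flat <- grayImage(matrix(100L, 5, 5))
  p <- predictPixel(flat, 3, 3)
  expect_true(p$embeddable)
  expect_equal(p$u, 100)
  expect_identical(p$d, 0L)

  m <- matrix(0L, 3, 3)
  m[1, 2] <- 10L; m[3, 2] <- 20L; m[2, 1] <- 30L; m[2, 3] <- 40L; m[2, 2] <- 20L
  p <- predictPixel(grayImage(m), 2, 2)
  expect_equal(p$u, 25)
  expect_identical(p$d, 5L)

  m <- matrix(0L, 3, 3); m[2, 3] <- 1L; m[2, 2] <- 1L
  p <- predictPixel(grayImage(m), 2, 2)          # u = 0.25, d = floor(-0.75)
  expect_equal(p$u, 0.25)
  expect_identical(p$d, -1L)

  expect_false(predictPixel(flat, 1, 3)$embeddable)  # border: a signal, not an error
})

test_that("the three-case error mapping matches the worked shifts", {
  expect_identical(mapError(5L), 8L)               # magnitude-3 shift above q
  expect_identical(mapError(-4L), -6L)             # magnitude-2 shift below p
  expect_identical(mapError(1L, bit = 0L), 2L)
  expect_identical(mapError(1L, bit = 1L), 3L)
  expect_identical(unmapError(-3L)$d, -2L)
  expect_identical(unmapError(-3L)$bit, 1L)        # mathematical mod on negatives
  expect_identical(unmapError(8L)$d, 5L)
  expect_true(is.na(unmapError(8L)$bit))
})

test_that("unmap(map(d, b)) is the identity over the full Table-3 range family", {
  d <- rep(-64:64, each = 2L)
  b <- rep_len(c(0L, 1L), length(d))
  for (p in seq(-20L, 0L, by = 2L)) for (q in seq(0L, 20L, by = 2L)) {
    D <- mapError(d, b, p, q)
    back <- unmapError(D, p, q)
    expect_identical(back$d, d)
    inr <- d >= p & d <= q
    expect_identical(back$bit[inr], b[inr])
    expect_true(all(is.na(back$bit[!inr])))
  }
})

test_that("embed/extract round trips reproduce payload and carrier exactly", {
  for (seed in c(1, 2, 3)) {
    img <- make_toy_carrier(seed)
    tm <- classifyBlocks(img, 5)
    set.seed(seed + 100)
    bits <- sample(0:1, 1000L, replace = TRUE)
    emb <- embedStream(img, tm, bits)
    expect_identical(payloadBits(emb$record), 1000L)
    ex <- extractStream(emb$stego, emb$record)
    expect_identical(ex$bits, as.integer(bits))
    expect_identical(pixelMatrix(ex$restored), pixelMatrix(img))
  }
})

test_that("smooth tiles are bit-identical between original and stego image", {
  img <- make_toy_carrier(9)
  px <- pixelMatrix(img)
  px[1:16, ] <- 120L                               # two smooth tile rows
  img <- grayImage(px)
  tm <- classifyBlocks(img, 5)
  set.seed(9)
  emb <- embedStream(img, tm, sample(0:1, 500, replace = TRUE))
  expect_identical(pixelMatrix(emb$stego)[1:16, ], px[1:16, ])
})

test_that("degenerate payloads and capacity violations behave as specified", {
  img <- make_toy_carrier(4)
  tm <- classifyBlocks(img, 5)
  emb <- embedStream(img, tm, integer(0))
  expect_identical(pixelMatrix(emb$stego), pixelMatrix(img))
  ex <- extractStream(emb$stego, emb$record)
  expect_identical(length(ex$bits), 0L)

  cap <- peeCapacity(img, tm)
  expect_error(embedStream(img, tm, rep(0L, cap + 1L)),
               class = "roicrypt_capacity_error")
  expect_error(embedStream(img, tm, rep(0L, cap + 1L), c(-2, 2)),
               regexp = "bits")

  # no embeddable tiles: empty stream in, image unchanged
  none <- classifyBlocks(grayImage(matrix(50L, 64, 64)), 5)
  emb0 <- embedStream(grayImage(matrix(50L, 64, 64)), none, integer(0))
  expect_identical(length(extractStream(emb0$stego, emb0$record)$bits), 0L)
})

test_that("extraction with a wrong error range cannot reproduce the payload", {
  img <- make_toy_carrier(12)
  tm <- classifyBlocks(img, 5)
  set.seed(12)
  bits <- sample(0:1, 800, replace = TRUE)
  emb <- embedStream(img, tm, bits, c(-2L, 2L))
  rec2 <- emb$record
  rec2@p <- -4L; rec2@q <- 4L
  got <- tryCatch(extractStream(emb$stego, rec2)$bits,
                  roicrypt_integrity_error = function(e) NULL)
  expect_false(identical(got, as.integer(bits)))
})

test_that("capacity equals a brute-force per-pixel count on a uniform toy", {
  # constant carrier: every error is 0 and a zero-bit embedding leaves pixels
  # unchanged, so the two-pass capacity equals the static interior count
  img <- grayImage(matrix(128L, 32, 32))
  mask <- matrix(TRUE, 4, 4)
  cap <- peeCapacity(img, mask, c(-2, 2))
  brute <- 0L
  for (r in 2:31) for (c in 2:31) brute <- brute + 1L   # full diamond inside
  expect_identical(cap, brute)

  # monotone in the range width on a textured phantom
  img2 <- generatePhantom(2, size = 256L, lesionTile = c(1L, 1L))
  tm <- classifyBlocks(img2, 5, keyRect = c(1L, 1L, 160L))
  caps <- sapply(c(2, 5, 10, 20), function(w) peeCapacity(img2, tm, c(-w, w)))
  expect_true(all(diff(caps) >= 0))
})

test_that("overflow-prone pixels go to the location map and stay reversible", {
  set.seed(55)
  px <- matrix(128L, 40, 40)
  px[9:24, 9:24] <- sample(251:255, 256, replace = TRUE)   # hugs the 255 rail
  img <- grayImage(px)
  tm <- classifyBlocks(img, 1)
  cap <- peeCapacity(img, tm)
  bits <- sample(0:1, max(cap %/% 2L, 1L), replace = TRUE)
  emb <- embedStream(img, tm, bits)
  expect_gt(length(locationMap(emb$record)), 0L)
  expect_true(all(pixelMatrix(emb$stego) >= 0L & pixelMatrix(emb$stego) <= 255L))
  ex <- extractStream(emb$stego, emb$record)
  expect_identical(ex$bits, as.integer(bits))
  expect_identical(pixelMatrix(ex$restored), px)
})
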