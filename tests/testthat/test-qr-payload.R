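# Metadata serialization, hybrid parameter encryption, and the matrix code
# block that replaces the key region.

make_record <- function(seed = 1L) {
  set.seed(seed)
  mask <- matrix(runif(64 * 64) < 0.5, 64, 64)
  new("PEERecord", p = -2L, q = 2L, payloadBits = 204800L,
      nEvenBits = 102400L,
      locationMap = sort(sample(512L * 512L, sample(0:20, 1))),
      tileMask = mask, blockSize = 8L, keyRect = c(161L, 161L, 160L),
      imageDim = c(512L, 512L))
}

make_params <- function(seed = 1L) {
  set.seed(seed + 1L)
  protectedParams(keyTile = c(161L, 161L), keySize = 160L,
                  threshold = runif(1, 0, 50), arnoldK = sample(1:5, 1),
                  record = make_record(seed),
                  scrambleMask = matrix(runif(64 * 64) < 0.8, 64, 64))
}

test_that("basic info serializes byte-stably and parses back", {
  txt <- serializeBasicInfo(fixture_info)
  expect_match(txt, "^Hospital: union hospital\n")
  expect_match(txt, "Image type: brain CT$")
  expect_equal(parseBasicInfo(txt), fixture_info)

  empty <- basicInfoRecord()
  expect_equal(parseBasicInfo(serializeBasicInfo(empty)), empty)
  expect_error(basicInfoRecord(hospital = "two\nlines"))
})

test_that("parameter encryption round-trips exactly, including the Arnold text", {
  pp <- make_params(3)
  expect_identical(pp@arnoldText, sprintf("8 x 8 %d", pp@arnoldK))
  ct <- encryptParams(pp, fixture_keys$pubkey)
  back <- decryptParams(ct, fixture_keys$key)
  expect_identical(back@arnoldText, pp@arnoldText)
  expect_identical(back@keyTile, pp@keyTile)
  expect_equal(back@threshold, pp@threshold)
  expect_identical(back@record@locationMap, pp@record@locationMap)
  expect_identical(back@record@tileMask, pp@record@tileMask)
  expect_identical(back@scrambleMask, pp@scrambleMask)
  expect_identical(back@record@payloadBits, 204800L)
})

test_that("a wrong private key or tampering yields no plaintext", {
  pp <- make_params(4)
  ct <- encryptParams(pp, fixture_keys$pubkey)
  wrong <- rsaKeyPair(2048L)
  expect_error(decryptParams(ct, wrong$key), class = "roicrypt_key_error")

  blob <- openssl::base64_decode(ct)
  blob[length(blob) - 3L] <- xor(blob[length(blob) - 3L], as.raw(1L))
  expect_error(decryptParams(openssl::base64_encode(blob), fixture_keys$key),
               class = "roicrypt_key_error")
})

test_that("render/decode round trips are exact for many random payloads", {
  set.seed(20)
  for (i in 1:100) {
    info <- basicInfoRecord(
      hospital = paste(sample(letters, sample(0:12, 1), TRUE), collapse = ""),
      doctorNumber = as.character(sample(1e4, 1)),
      imageType = sample(c("brain CT", "lung CT", "MRI", ""), 1))
    ct <- openssl::base64_encode(openssl::rand_bytes(sample(1:1200, 1)))
    pay <- codePayload(info, ct, c(sample(353, 1), sample(353, 1)))
    blk <- renderCodeBlock(pay)
    expect_identical(dim(blk), c(160L, 160L))
    expect_true(all(pixelMatrix(blk) %in% c(0L, 255L)))
    back <- decodeCodeBlock(blk)
    expect_equal(basicInfo(back), info)
    expect_identical(ciphertext(back), ct)
    expect_identical(keyTile(back), keyTile(pay))
  }
})

test_that("the canonical block is 160 x 160 = 25,600 pixels", {
  blk <- renderCodeBlock(codePayload(fixture_info, "QQ==", c(1L, 1L)))
  expect_identical(length(pixelMatrix(blk)), 25600L)
})

test_that("scrambled, natural, or oversize payloads fail loudly", {
  pay <- codePayload(fixture_info,
                     openssl::base64_encode(openssl::rand_bytes(800)), c(161L, 161L))
  blk <- renderCodeBlock(pay)
  expect_error(decodeCodeBlock(scrambleBlock(blk, 2)),
               class = "roicrypt_decode_error")
  natural <- extractBlock(generatePhantom(1), c(161L, 161L), 160L)
  expect_error(decodeCodeBlock(natural), class = "roicrypt_decode_error")
  big <- codePayload(fixture_info,
                     openssl::base64_encode(openssl::rand_bytes(2800)), c(1L, 1L))
  expect_error(renderCodeBlock(big), class = "roicrypt_capacity_error")
})

test_that("code blocks are located on and off the 160 grid", {
  pay <- codePayload(fixture_info,
                     openssl::base64_encode(openssl::rand_bytes(500)), c(161L, 321L))
  blk <- renderCodeBlock(pay)
  img <- generatePhantom(2)
  onGrid <- writeBlock(img, c(161L, 321L), blk)
  hit <- locateCodeBlock(onGrid)
  expect_identical(hit$tile, c(161L, 321L))
  expect_identical(ciphertext(hit$payload), ciphertext(pay))

  offGrid <- writeBlock(img, c(101L, 87L), blk)
  hit <- locateCodeBlock(offGrid)
  expect_identical(hit$tile, c(101L, 87L))

  expect_error(locateCodeBlock(img), class = "roicrypt_decode_error")
})
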