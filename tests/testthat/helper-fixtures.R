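# Shared fixtures, built in code at test time.

fixture_keys <- rsaKeyPair(2048L)

fixture_info <- basicInfoRecord(
  hospital = "union hospital", department = "internal medicine",
  doctorNumber = "526", patientNumber = "10,256", shootingTime = "9/6",
  contactNumber = "5628***", imageType = "brain CT")

# a small band-limited carrier (every 8x8 tile has MSE well above 5, while
# prediction errors concentrate near zero, as in real CT) whose values stay
# far from 0/255, so embeddings never need the location map
make_toy_carrier <- function(seed, size = 64L) {
  set.seed(seed)
  r <- matrix(seq_len(size), size, size)
  cc <- t(r)
  px <- 128 + 8 * sin(2 * pi * (r / 9 + cc / 13)) +
    5 * sin(2 * pi * (r / 11 - cc / 7)) +
    matrix(stats::rnorm(size * size, 0, 0.7), size, size)
  grayImage(matrix(pmin(pmax(round(px), 0L), 255L), size, size))
}

# brute-force tile variance, the independent oracle for blockMSE/classify
naive_tile_var <- function(px, b) {
  ntr <- nrow(px) %/% b; ntc <- ncol(px) %/% b
  out <- matrix(0, ntr, ntc)
  for (i in seq_len(ntr)) for (j in seq_len(ntc)) {
    blk <- px[((i - 1L) * b + 1L):(i * b), ((j - 1L) * b + 1L):(j * b)]
    out[i, j] <- mean((blk - mean(blk))^2)
  }
  out
}
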