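# Arnold cat-map scrambling of pixel positions within square blocks.
#
# The map (x, y) -> (x + y, x + 2y) mod N is a bijection of the N x N
# lattice and is periodic: after period(N) applications every point returns
# home. Scrambling k times is inverted either by period(N) - k forward steps
# or by k applications of the inverse matrix [[2, -1], [-1, 1]] mod N; the
# implementation uses the inverse matrix. Lattice coordinates are 0-based,
# matching the map's modular arithmetic; x indexes rows, y columns.

#' One Arnold cat-map step
#'
#' @param x,y 0-based lattice coordinates in [0, N).
#' @param N lattice order (block side length).
#' @return list with transformed coordinates \code{x}, \code{y}.
#' @examples
#' arnoldStep(1, 1, 8)  # (2, 3)
#' @export
arnoldStep <- function(x, y, N) {
  stopifnot(all(x >= 0 & x < N), all(y >= 0 & y < N))
  list(x = (x + y) %% N, y = (x + 2 * y) %% N)
}

#' Period of the Arnold map on an N x N lattice
#'
#' Smallest k >= 1 such that k applications are the identity, computed as the
#' multiplicative order of the matrix [[1, 1], [1, 2]] modulo N. The period
#' depends on N (e.g. it differs between 8 x 8 blocks and whole images),
#' which is why the iteration count must travel with the encrypted image.
#'
#' @param N lattice order, N >= 2.
#' @return integer period.
#' @export
arnoldPeriod <- function(N) {
  N <- as.integer(N)
  stopifnot(N >= 2L)
  M <- matrix(c(1L, 1L, 1L, 2L), 2L, 2L)   # column-major: [[1,1],[1,2]]
  A <- M
  k <- 1L
  while (!(A[1L, 1L] %% N == 1L && A[2L, 2L] %% N == 1L &&
           A[1L, 2L] %% N == 0L && A[2L, 1L] %% N == 0L)) {
    A <- (A %*% M) %% N
    k <- k + 1L
  }
  k
}

# k-step destination permutation: perm[i] is the 1-based column-major lattice
# index that position i maps to after k forward steps.
.arnold_perm <- function(N, k, inverse = FALSE) {
  idx <- seq_len(N * N)
  x <- (idx - 1L) %% N          # row, 0-based
  y <- (idx - 1L) %/% N         # col, 0-based
  k <- k %% arnoldPeriod(N)
  for (i in seq_len(k)) {
    if (inverse) {
      t <- (2L * x - y) %% N    # inverse matrix [[2, -1], [-1, 1]]
      y <- (y - x) %% N
      x <- t
    } else {
      t <- (x + y) %% N
      y <- (x + 2L * y) %% N
      x <- t
    }
  }
  y * N + x + 1L
}

.apply_perm_block <- function(px, perm) {
  out <- px
  out[perm] <- px
  out
}

#' Scramble or unscramble one square block
#'
#' Applies k Arnold steps to the pixel positions of a square block (pixel at
#' (x, y) moves to the k-fold image of (x, y)); \code{unscrambleBlock} applies
#' the inverse permutation. The pixel-value multiset is preserved.
#'
#' @param block a square \linkS4class{GrayImage}.
#' @param k number of iterations, k >= 0.
#' @return a \linkS4class{GrayImage}.
#' @export
scrambleBlock <- function(block, k) {
  stopifnot(is(block, "GrayImage"))
  d <- dim(block@pixels)
  if (d[1L] != d[2L])
    .rc_error("roicrypt_bounds_error", "Arnold scrambling requires a square block")
  grayImage(.apply_perm_block(block@pixels, .arnold_perm(d[1L], as.integer(k))))
}

#' @rdname scrambleBlock
#' @export
unscrambleBlock <- function(block, k) {
  stopifnot(is(block, "GrayImage"))
  d <- dim(block@pixels)
  if (d[1L] != d[2L])
    .rc_error("roicrypt_bounds_error", "Arnold scrambling requires a square block")
  grayImage(.apply_perm_block(block@pixels, .arnold_perm(d[1L], as.integer(k),
                                                         inverse = TRUE)))
}

# Apply the k-step (or inverse) permutation to every tile in tileMask at
# once: tiles are gathered into an N^2 x nTiles matrix, rows permuted, and
# scattered back.
.scramble_tiles <- function(px, tileMask, b, k, inverse) {
  sel <- which(tileMask)
  if (length(sel) == 0L || k %% arnoldPeriod(b) == 0L) return(px)
  ntr <- nrow(tileMask)
  tr <- (sel - 1L) %% ntr
  tc <- (sel - 1L) %/% ntr
  H <- nrow(px)
  # linear indices of each tile's pixels, column-major within the tile
  offs <- as.vector(outer(seq_len(b), (seq_len(b) - 1L) * H, "+")) - 1L
  base <- (tc * b) * H + tr * b + 1L
  idx <- outer(offs, base, "+")                 # b^2 x nTiles
  vals <- matrix(px[idx], nrow = b * b)
  perm <- .arnold_perm(b, as.integer(k), inverse = inverse)
  out <- vals
  out[perm, ] <- vals
  px[idx] <- out
  px
}

#' Scramble the texture area of an image
#'
#' Applies k Arnold iterations within every tile of the scramble set,
#' leaving all other pixels untouched. \code{unscrambleRegion} restores the
#' original exactly. The whole-image histogram is preserved (positions move,
#' values do not).
#'
#' @param image a \linkS4class{GrayImage}.
#' @param tileMask logical tile matrix (e.g. \code{scrambleMask(textureMap)}),
#'   or a \linkS4class{TextureMap} whose scramble set is used. Must exclude
#'   key-region/code-block tiles.
#' @param k number of Arnold iterations (default 4).
#' @param blockSize tile side (default 8); ignored when a TextureMap is given.
#' @return a \linkS4class{GrayImage}.
#' @export
scrambleRegion <- function(image, tileMask, k = 4L, blockSize = 8L) {
  stopifnot(is(image, "GrayImage"))
  if (is(tileMask, "TextureMap")) {
    blockSize <- tileMask@blockSize
    tileMask <- tileMask@scramble
  }
  grayImage(.scramble_tiles(image@pixels, tileMask, as.integer(blockSize),
                            as.integer(k), inverse = FALSE))
}

#' @rdname scrambleRegion
#' @export
unscrambleRegion <- function(image, tileMask, k = 4L, blockSize = 8L) {
  stopifnot(is(image, "GrayImage"))
  if (is(tileMask, "TextureMap")) {
    blockSize <- tileMask@blockSize
    tileMask <- tileMask@scramble
  }
  grayImage(.scramble_tiles(image@pixels, tileMask, as.integer(blockSize),
                            as.integer(k), inverse = TRUE))
}
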