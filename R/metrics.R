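# Image quality metrics: PSNR and SSIM for 8-bit grayscale images.

#' Peak signal-to-noise ratio
#'
#' PSNR = 10 log10(255^2 / MSE) over all pixels; +Inf for identical images,
#' which together with SSIM = 1 certifies bit-exact recovery.
#'
#' @param a,b \linkS4class{GrayImage}s of equal dimensions.
#' @return PSNR in dB (possibly \code{Inf}).
#' @export
psnr <- function(a, b) {
  stopifnot(is(a, "GrayImage"), is(b, "GrayImage"))
  if (!identical(dim(a@pixels), dim(b@pixels)))
    .rc_error("roicrypt_bounds_error", "images must share dimensions")
  mse <- mean((a@pixels - b@pixels)^2)
  if (mse == 0) Inf else 10 * log10(255^2 / mse)
}

# window sums over all w x w positions via an integral image
.box_sums <- function(M, w) {
  H <- nrow(M); W <- ncol(M)
  I <- matrix(0, H + 1L, W + 1L)
  I[-1L, -1L] <- apply(M, 2L, cumsum)
  I <- t(apply(I, 1L, cumsum))
  I[(w + 1L):(H + 1L), (w + 1L):(W + 1L)] -
    I[1:(H - w + 1L), (w + 1L):(W + 1L)] -
    I[(w + 1L):(H + 1L), 1:(W - w + 1L)] +
    I[1:(H - w + 1L), 1:(W - w + 1L)]
}

#' Structural similarity index
#'
#' Mean SSIM over all sliding windows, with an 8x8 uniform window (matching
#' the block size used throughout the scheme), dynamic range L = 255 and the
#' standard stabilizing constants K1 = 0.01, K2 = 0.03. Symmetric in its
#' arguments; exactly 1 for identical images.
#'
#' @param a,b \linkS4class{GrayImage}s of equal dimensions.
#' @param window window side (default 8).
#' @return SSIM value in [-1, 1].
#' @export
ssim <- function(a, b, window = 8L) {
  stopifnot(is(a, "GrayImage"), is(b, "GrayImage"))
  if (!identical(dim(a@pixels), dim(b@pixels)))
    .rc_error("roicrypt_bounds_error", "images must share dimensions")
  w <- as.integer(window)
  A <- a@pixels * 1.0
  B <- b@pixels * 1.0
  n <- w * w
  muA <- .box_sums(A, w) / n
  muB <- .box_sums(B, w) / n
  vA <- .box_sums(A * A, w) / n - muA^2
  vB <- .box_sums(B * B, w) / n - muB^2
  cab <- .box_sums(A * B, w) / n - muA * muB
  C1 <- (0.01 * 255)^2
  C2 <- (0.03 * 255)^2
  mean(((2 * muA * muB + C1) * (2 * cab + C2)) /
         ((muA^2 + muB^2 + C1) * (vA + vB + C2)))
}

#' PSNR and SSIM in one call
#'
#' @inheritParams psnr
#' @return named list with elements \code{psnr} and \code{ssim}.
#' @export
imageQuality <- function(a, b) {
  list(psnr = psnr(a, b), ssim = ssim(a, b))
}
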