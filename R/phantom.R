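# Seeded generator of synthetic medical-style grayscale phantoms.
#
# A phantom emulates the features of the CT slices the scheme targets: a
# large organ-like body occupying most of the frame, band-limited texture
# inside it (so prediction errors concentrate near zero, as in real CT), a
# darker background, and one high-variance lesion patch engineered to win
# the coefficient-of-variation argmax. Everything is deterministic for a
# fixed seed; no external data are needed anywhere in the package.

# bilinear upsampling of a coarse standard-normal grid to H x W
.smooth_field <- function(H, W, step) {
  gr <- ceiling(H / step) + 2L
  gc <- ceiling(W / step) + 2L
  G <- matrix(stats::rnorm(gr * gc), gr, gc)
  fr <- (seq_len(H) - 1L) / step
  fc <- (seq_len(W) - 1L) / step
  i0 <- floor(fr); j0 <- floor(fc)
  ai <- fr - i0; aj <- fc - j0
  G00 <- G[i0 + 1L, j0 + 1L, drop = FALSE]
  G10 <- G[i0 + 2L, j0 + 1L, drop = FALSE]
  G01 <- G[i0 + 1L, j0 + 2L, drop = FALSE]
  G11 <- G[i0 + 2L, j0 + 2L, drop = FALSE]
  t(t(G00 * (1 - ai) + G10 * ai) * (1 - aj)) +
    t(t(G01 * (1 - ai) + G11 * ai) * aj)
}

# 3x3 box smoothing with edge replication
.box3 <- function(M) {
  H <- nrow(M); W <- ncol(M)
  Mp <- M[c(1L, seq_len(H), H), c(1L, seq_len(W), W)]
  acc <- matrix(0, H, W)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + Mp[dr + seq_len(H), dc + seq_len(W)]
  acc / 9
}

#' Generate a lesion-bearing phantom image
#'
#' Deterministic for a fixed seed. The image contains a bright, softly
#' shaded elliptical body covering most of the frame, smooth stochastic
#' sinusoidal texture of spatially varying amplitude inside it, a dark
#' background with optional low-amplitude noise, and a high-contrast speckle
#' lesion centered in the requested 160-grid tile. After generation, the
#' lesion tile's coefficient of variation is verified to dominate every
#' other tile's; if not, the lesion contrast is boosted and the patch
#' regenerated.
#'
#' @param seed integer RNG seed.
#' @param size image side in pixels (default 512).
#' @param lesionTile integer(2) tile coordinates on the \code{keySize} grid
#'   (default the center tile of a 512 image, c(2, 2)).
#' @param lesionContrast speckle amplitude multiplier (1 = default contrast
#'   of about 105 gray levels); 0 is rejected, since a flat patch can never
#'   dominate the argmax.
#' @param backgroundTexture standard deviation of the (smoothed) background
#'   noise in gray levels; 0 yields an exactly constant background whose
#'   8x8 tiles have MSE 0.
#' @param textureAmplitude numeric(2), range of the organ texture amplitude
#'   in gray levels; per-tile MSE is roughly amplitude^2 / 2.
#' @param edgeWidth softness of the organ boundary in pixels.
#' @param keySize key-region side defining the lesion grid (default 160).
#' @return a \linkS4class{GrayImage}.
#' @examples
#' img <- generatePhantom(1, size = 512)
#' keyTile(selectKeyRegion(img))   # (161, 161): the center tile
#' @export
generatePhantom <- function(seed, size = 512L, lesionTile = c(2L, 2L),
                            lesionContrast = 1, backgroundTexture = 1,
                            textureAmplitude = c(3.8, 12), edgeWidth = 3,
                            keySize = 160L) {
  size <- as.integer(size)
  set.seed(as.integer(seed))
  H <- size; W <- size
  anchor <- (as.integer(lesionTile) - 1L) * keySize + 1L
  if (any(anchor < 1L) || any(anchor + keySize - 1L > size))
    .rc_error("roicrypt_bounds_error", "lesionTile outside the key-region grid")
  r <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)

  # body: softly shaded ellipse covering most of the frame
  rho <- sqrt(((r - H / 2) / (0.58 * H))^2 + ((cc - W / 2) / (0.55 * W))^2)
  wgt <- 1 / (1 + exp((rho - 1) * (0.58 * H) / max(edgeWidth, 0.5)))
  base <- 70 + wgt * (135 - 25 * pmin(rho, 1)^2 - 70)

  # organ texture: two incommensurate sinusoids under a smooth amplitude
  # field; per-tile variance approx amplitude^2 / 2
  u <- stats::pnorm(.smooth_field(H, W, 64L))
  amp <- textureAmplitude[1L] +
    (textureAmplitude[2L] - textureAmplitude[1L]) * u^0.4
  ph <- stats::runif(2L, 0, 2 * pi)
  tex <- amp * (0.8 * sin(2 * pi * (r / 23 + cc / 31) + ph[1L]) +
                0.6 * sin(2 * pi * (r / 17 - cc / 29) + ph[2L]))
  fine <- matrix(stats::rnorm(H * W, 0, 0.5), H, W)
  bg <- if (backgroundTexture > 0)
    .box3(matrix(stats::rnorm(H * W, 0, backgroundTexture * 1.7), H, W)) else 0

  img <- base + wgt * (tex + fine) + (1 - wgt) * bg

  # lesion: high-contrast speckle disk centered in the target tile
  ctr <- anchor + keySize / 2
  disk <- which((r - ctr[1L])^2 + (cc - ctr[2L])^2 <= (0.47 * keySize)^2)
  contrast <- lesionContrast
  for (attempt in 1:8) {
    if (contrast <= 0)
      .rc_error("roicrypt_format_error",
                "lesionContrast 0 cannot satisfy the Cv-dominance requirement")
    out <- img
    spots <- sample(c(-1, 1), length(disk), replace = TRUE)
    out[disk] <- 130 + spots * 105 * contrast
    out <- matrix(pmin(pmax(round(out), 0L), 255L), H, W)
    gi <- grayImage(out)
    mo <- .tile_moments(out, as.integer(keySize))
    cv <- sqrt(pmax(mo$var, 0)) / ifelse(mo$mean > 0, mo$mean, Inf)
    ti <- (as.integer(lesionTile))
    lesionCv <- cv[ti[1L], ti[2L]]
    cv[ti[1L], ti[2L]] <- -Inf
    if (lesionCv > 1.1 * max(cv)) return(gi)
    contrast <- contrast * 1.3          # boost and regenerate the patch
  }
  .rc_error("roicrypt_format_error",
            "could not construct a Cv-dominant lesion for this specification")
}

#' Generate a suite of phantoms
#'
#' \code{n} phantoms with consecutive seeds and varied lesion positions and
#' contrasts, for property-style testing of the full pipeline.
#'
#' @param n number of phantoms (>= 1).
#' @param baseSeed seed of the first phantom; phantom i uses
#'   \code{baseSeed + i - 1}.
#' @param size image side (default 512).
#' @return list of \linkS4class{GrayImage}s.
#' @export
generateSuite <- function(n, baseSeed = 1L, size = 512L) {
  stopifnot(n >= 1L)
  nt <- size %/% 160L
  lapply(seq_len(n), function(i) {
    tile <- c((i - 1L) %% nt + 1L, ((i - 1L) %/% nt) %% nt + 1L)
    generatePhantom(baseSeed + i - 1L, size = size, lesionTile = tile,
                    lesionContrast = 0.9 + 0.05 * (i %% 5L))
  })
}
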