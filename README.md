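# roicrypt

Partial encryption of medical images with reversible key-region hiding.

Medical images shared over open networks need two things at once: the
diagnostically sensitive region must be unreadable to anyone without
authorization, and the image must remain retrievable — searchable, triaged,
attributable — without giving that sensitivity away. `roicrypt` implements a
partial-protection scheme for 8-bit grayscale images that does both, and
whose decryption is *lossless*: the restored image is bit-identical to the
original, which full-image encryption plus ordinary watermarking cannot
guarantee. It is aimed at researchers and engineers working on medical
image security, and at anyone who needs a reproducible reference
implementation of reversible data hiding by prediction-error expansion.

## The method

For an image `I` (canonically 512 x 512):

1. **Key region** — tile at 160 x 160 and pick the block maximizing the
   coefficient of variation

   C_v = σ / μ,  σ = sqrt( (1/N) Σ (x_i − μ)² ),

   the normalized dispersion that lesion-bearing, texture-rich blocks
   maximize. A clinician can override the choice.
2. **Texture area** — tile at 8 x 8; a block is embeddable when its
   MSE = (1/mn) ΣΣ [I(i,j) − I_ave(i,j)]² (its variance) exceeds a
   threshold `T`.
3. **Reversible hiding** — the key region's 204,800 bits are embedded in
   the texture area by prediction-error expansion: predict each pixel from
   its four neighbors, u = (v_left + v_right + v_up + v_down)/4,
   d = ⌊u − v⌋, then

   D = 2d + b      if d ∈ [p, q]      (carries payload bit b)
   D = d + q + 1   if d > q           (histogram shift, +3 at [−2, 2])
   D = d + p       if d < p           (histogram shift, −2 at [−2, 2])

   with the stego pixel v′ = v + (d − D). Extraction reads b = D mod 2 and
   restores v exactly.
4. **Scrambling** — every 8 x 8 block with MSE > 0 is permuted in place by
   k iterations of the Arnold cat map (x, y) → (x + y, x + 2y) mod 8.
5. **Replacement** — a 160 x 160 matrix-code block overwrites the key
   region: cleartext patient/image metadata, plus the descrambling
   parameters encrypted under the recipient's RSA public key.

Decryption inverts everything in reverse order; the round trip is
pixel-exact (PSNR = ∞, SSIM = 1). Without the private key, forcibly reading
the embedded bits from the still-scrambled image yields an unrecognizable
block (SSIM < 0.1 against the true lesion).

## Worked example

```r
library(roicrypt)

keys <- rsaKeyPair()                      # RSA-2048 key pair
info <- basicInfoRecord(
  hospital = "union hospital", department = "internal medicine",
  doctorNumber = "526", patientNumber = "10,256", shootingTime = "9/6",
  contactNumber = "5628***", imageType = "brain CT")

img <- generatePhantom(1)                 # seeded 512 x 512 lesion phantom
selectKeyRegion(img)
#> KeyRegionStats: tile (161, 161) size 160 | mu 130.165 sigma 87.617 Cv 0.6731

enc <- encryptImage(img, info, keys$pubkey)
enc
#> EncryptionResult: 512 x 512 image, code block at (161, 161) size 160
#>   T = 5, error range [-2, 2], Arnold k = 4, 204800 bits embedded
```

The lesion tile at (161, 161) wins the C_v argmax (0.67 against ≤ 0.31 for
every other tile), the full 204,800-bit key stream fits at the default
error range [−2, 2], and the protected image keeps the input's dimensions.
Against the original it measures PSNR ≈ 14.4 dB, SSIM ≈ 0.58 — degraded
enough to hide content, structured enough to recognize the image in an
archive. Anyone can read the metadata without a key:

```r
inspectCodeBlock(pixelMatrix(enc) |> grayImage())
#> Hospital: union hospital
#> ...
#> Image type: brain CT
```

Authorized decryption is exact, keyless extraction is not:

```r
dec <- decryptImage(enc, keys$key)
identical(pixelMatrix(dec), pixelMatrix(img))
#> TRUE                                    # PSNR Inf, SSIM 1

truth <- extractBlock(img, keyTile(enc), 160)
ssim(truth, unauthorizedReconstruction(enc))
#> 0.0039                                  # and PSNR 5.4 dB: noise
```

A command-line interface wrapping these functions (subcommands `keygen`,
`phantom`, `encrypt`, `decrypt`, `inspect-qr`, `metrics`) is installed at
`system.file("cli", "roicrypt", package = "roicrypt")`.

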