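---
title: "Key-region protection of medical images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Key-region protection of medical images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roicrypt)
```

## The problem

Medical images carry two kinds of sensitive content: the diagnostic finding
itself (a lesion) and the patient metadata around it. Full-image encryption
protects both but makes images unsearchable in an archive and fragile in
transit; plain watermarking protects neither. `roicrypt` implements a
partial-protection scheme: the lesion-bearing *key region* is removed from
the image and hidden, reversibly, inside the image's own textured areas; the
vacated region is replaced by a machine-readable block carrying cleartext
metadata plus encrypted recovery parameters. Anyone can retrieve and triage
the image; only a holder of the RSA private key can reconstruct the original,
bit for bit.

## Pipeline

Encryption proceeds in five stages on an 8-bit grayscale image (canonically
512 x 512):

1. **Key-region selection.** The image is tiled into 160 x 160 blocks and the
   block with the largest coefficient of variation
   $C_v = \sigma / \mu$, with $\sigma$ the population (1/N) standard
   deviation, is taken as the key region. $C_v$ is a normalized dispersion
   measure: lesions are texture-rich, so they score high, while uniformly
   dark or bright anatomy scores low. An all-black block has $C_v$ defined
   as 0 so empty background can never win. Ties break by row-major order. A
   clinician can override the choice with any in-bounds anchor
   (`overrideKeyRegion`), on or off the grid.
2. **Texture classification.** The full image is tiled at 8 x 8 and each
   tile's mean squared error about its own mean (equal to its population
   variance) is compared with a threshold $T$: tiles with $\mathrm{MSE} > T$
   are *texture* (embeddable), the rest *smooth*. Tiles overlapping the key
   region are excluded: that area is about to be replaced, not used as a
   carrier.
3. **Reversible embedding.** The key region's 25,600 pixels become a
   204,800-bit stream and are embedded into the texture area by
   prediction-error expansion (below). Smooth tiles are never modified.
4. **Scrambling.** Every 8 x 8 tile with $\mathrm{MSE} > 0$ on the
   *post-embedding* image is scrambled in place with $k$ iterations of the
   Arnold cat map, destroying local structure while preserving the
   histogram and the image outline.
5. **Replacement.** A 160 x 160 matrix-code block carrying the cleartext
   metadata and the RSA-protected parameter bundle overwrites the key
   region. The output has exactly the input's dimensions.

Decryption inverts the stages in reverse: decode the block, unwrap the
parameters, unscramble, extract and restore, reassemble the key region.
The round trip is pixel-exact (PSNR infinite, SSIM exactly 1).

## Prediction-error expansion

Each candidate pixel $v_{i,j}$ is predicted from its four
horizontal/vertical neighbors (the diamond predictor),

$$u_{i,j} = \tfrac14 (v_{i,j-1} + v_{i,j+1} + v_{i-1,j} + v_{i+1,j}),
\qquad d_{i,j} = \lfloor u_{i,j} - v_{i,j} \rfloor ,$$

with $\lfloor\cdot\rfloor$ the floor toward $-\infty$ (computed exactly in
integer arithmetic as `(s - 4v) %/% 4`). Errors inside the selection range
$[p, q]$ (default $[-2, 2]$) are expanded to carry one payload bit $b$;
errors outside are shifted by a constant so the two populations stay
disjoint:

$$D_{i,j} = \begin{cases}
2 d_{i,j} + b, & d_{i,j} \in [p, q] \\
d_{i,j} + q + 1, & d_{i,j} > q \\
d_{i,j} + p, & d_{i,j} < p .
\end{cases}$$

With the default range, the two shifts have magnitude $q+1 = 3$ and
$|p| = 2$. The stego pixel is $v' = v + (d - D)$; this is the unique update
consistent with the floor-based error definition, because re-predicting on
the stego image returns exactly $D$ (the fractional part of $u - v$ is
preserved), after which $b = D \bmod 2$, $d = \lfloor D/2 \rfloor$ and
$v = v' + (D - d)$ invert everything. The package verifies
$\mathrm{unmap} \circ \mathrm{map} = \mathrm{id}$ exhaustively over
$d \in [-64, 64]$ and the whole range family $[-2,2] \ldots [-20,20]$.

Design choices that make the embedding exactly reversible at scale:

* **Two global checkerboard layers.** All pixels with $(r + c)$ even are
  embedded first, then the odd layer. Within a layer every predictor
  belongs to the *other* parity, so a layer never perturbs its own
  predictions; the decoder replays the layers in reverse (odd first, its
  predictors being the even pixels exactly as the encoder left them) and
  restores each layer before using it to predict the next. Within a layer,
  targets are visited in a canonical column-major order that the decoder can
  reproduce from the carried tile set alone.
* **Image-wide prediction.** The diamond may cross 8 x 8 tile boundaries:
  smooth neighbors are never modified, scrambling is fully inverted before
  extraction, and pixels whose diamond touches the key rectangle (whose
  content is replaced by the code block) are excluded. Restricting
  prediction to tile interiors would cap capacity at
  $36 \cdot (4096 - 400) = 133{,}056$ bits — below the 204,800-bit key
  stream — so tile-local embedding cannot satisfy the lossless contract on
  a 512 x 512 image; image-wide prediction offers up to ~234,000 target
  pixels.
* **Location map.** A pixel whose modified value would leave $[0, 255]$ is
  recorded and left untouched; the decoder skips mapped pixels
  unconditionally. Because the skip set changes the bit assignment which in
  turn decides which pixels are at risk, the encoder resolves the set by a
  monotone fixed-point iteration (each round is vectorized; the set only
  grows, so it terminates). On generated phantoms the map is empty — pixel
  values stay away from the rails — but the mechanism is exercised by tests
  that hug the 255 rail.
* **Stop semantics.** The encoder stops at the pixel consuming the final
  payload bit; everything after it is untouched. The record therefore
  carries the total bit count *and* the even-layer bit count, so the
  decoder stops at exactly the same pixel in each layer.

### Capacity and the effective threshold

`peeCapacity` is defined operationally as a dry-run embedding of an all-zero
stream: the second layer is predicted from the modified first layer, so
capacity is a property of the full two-pass procedure, not a static count
(the two coincide on constant carriers, which is how the brute-force oracle
test is built). When $\{\mathrm{MSE} > T\}$ cannot hold the payload, the
encoder adds further tiles in descending-MSE order — equivalently, lowers
the effective threshold below $T$ — until the payload fits. This
generalizes the scheme's stated fallback of automatically selecting the
maximal-MSE block when $T$ exceeds every block's MSE, and it is what makes
the threshold sweep well defined at large $T$: past the point where the
requested threshold is binding, the embedded set is capacity-driven and
constant, so the encrypted image's PSNR/SSIM plateau. Only if even the full
grid is insufficient at the requested range does the encoder widen the
range symmetrically, $[-3,3], [-4,4], \ldots, [-20,20]$, before failing
with a capacity error that names the required and available bits.

## Arnold scrambling

The cat map $(x, y) \mapsto (x + y,\ x + 2y) \bmod N$ is a bijection of the
$N \times N$ lattice with a period that depends on $N$; `arnoldPeriod`
computes it as the multiplicative order of
$\left[\begin{smallmatrix}1&1\\1&2\end{smallmatrix}\right]$ mod $N$, and a
brute-force lattice iteration confirms it in the tests. Scrambling uses
8 x 8 blocks (so block boundaries cannot collide with the 160-grid of the
key region) and defaults to $k = 4$ iterations — the "8 x 8 4" parameter
string carried in the protected payload — with $k$ freely configurable.
Unscrambling applies the inverse matrix
$\left[\begin{smallmatrix}2&-1\\-1&1\end{smallmatrix}\right]$ mod $N$, which
the tests check against $\mathrm{period}(N) - k$ forward steps. The
scramble set is evaluated on the post-embedding image and carried in the
protected payload rather than recomputed at decode time: embedding shifts
can move a tile's MSE across 0 (or $T$), and carrying the sets is the only
way to guarantee encoder/decoder agreement, hence losslessness.

## The code block and its cryptography

The replacement block is a compact binary matrix code designed for this
pipeline: a 4-pixel quiet border, a 2-pixel frame, and a 148 x 148 data
field at one pixel per module — 2,718 payload bytes inside the canonical
160 x 160 region. The field carries a magic word, a length, an 8-byte
SHA-256 truncation of the body, the body (cleartext metadata in "Label:
value" lines, the key-region anchor, and the parameter ciphertext), then
deterministic hash-chain padding. Any bit damage fails the checksum, which
is the machine-readable signal that a protected image has been tampered
with. The decoder scans the 160-grid anchors first and falls back to an
exhaustive magic-bit scan, so manually placed off-grid regions are found
too.

The parameter bundle (Arnold text, key anchor, threshold, error range,
tile and scramble masks, location map, bit counts) is protected with a
hybrid scheme: AES-256-CTR under a content key, sealed encrypt-then-MAC
with HMAC-SHA256, the content key RSA-wrapped with the recipient's public
key. Two deliberate choices:

* **Explicit MAC rather than relying on the cipher.** The MAC is checked
  before any plaintext is parsed; a wrong private key or a flipped
  ciphertext bit fails closed. (OpenSSL 3 deliberately returns garbage
  rather than an error for wrong-key RSA decryption, so an explicit
  integrity check is the only reliable failure signal.)
* **Convergent content keys.** The content key and nonce are derived by
  hashing the serialized parameters, so identical parameter bundles
  encrypt identically and the pipeline is reproducible run to run; only
  the RSA-OAEP key wrap is randomized. The trade-off is standard for
  convergent encryption: an observer can tell that two protected images
  used identical parameters. The parameters contain no patient data, so
  this leak was judged acceptable for a scientific tool whose outputs must
  be auditable.

## The phantom generator

No external image archive is required anywhere in the package: a seeded
generator produces lesion-bearing phantoms emulating the features the
scheme relies on in real CT — a body occupying most of the frame,
band-limited texture (so prediction errors concentrate near zero, which is
what gives PEE its capacity), a darker background, and a single
high-contrast lesion. Concretely: a softly shaded ellipse (background level
70, body 110–135) covering roughly nine-tenths of the frame; two
incommensurate sinusoids under a smooth random amplitude field of 3.8–12
gray levels (per-tile MSE about amplitude²/2, spanning the 5–50 sweep
range); Gaussian fine noise of 0.5 gray levels; and a speckle disk of
±105·contrast gray levels filling about 70 % of the target 160-tile. After
generation the lesion tile's $C_v$ is verified to dominate every other tile
by at least 10 %; otherwise the contrast is boosted and the patch
regenerated, and a flat patch (contrast 0) is rejected outright. The body
must fill most of the frame for a structural reason: the 204,800-bit key
stream needs roughly 88 % of all non-key pixels as targets, exactly the
regime the scheme's source imagery (organ-filling CT slices) occupies.

What the phantoms do *not* emulate: anatomical structure, modality-specific
noise spectra, bit depths above 8, and lesions that straddle grid tiles.
Passing tests therefore demonstrate the algorithmic contracts (exact
reversibility, capacity, degradation of unauthorized access) under
realistic texture statistics, not clinical detection performance.

A second configuration (`textureAmplitude = c(3.5, 7.2)`, `edgeWidth = 32`,
soft everything) bounds every usable block's MSE below ~30 so that the
threshold sweep's plateau regime is actually reachable inside the 5–50
sweep; with the default configuration, organ-boundary tiles keep large MSEs
and the plateau would lie beyond it.

## Numerical choices and degenerate inputs

* Floors and moduli use the toward-$-\infty$ / always-non-negative
  conventions on negative operands, stated explicitly because language
  defaults differ; R's `%/%` and `%%` already comply.
* All coordinates are 1-based (row, col) with the origin at the top-left,
  the R idiom; Arnold lattice coordinates are 0-based as in the map's
  arithmetic.
* A uniform image: every $C_v$ is 0, tile (1, 1) wins by tie-break; the
  texture and scramble sets are empty; an empty payload embeds and extracts
  as a no-op.
* Ties in MSE ordering break by row-major tile index
  (`embeddableTiles`); ties in the $C_v$ argmax by row-major tile order.
* Images smaller than 160 x 160 are rejected for encryption; color or
  >8-bit inputs are rejected at read time rather than silently converted.
* The test suite and the acceptance script use 512 x 512 phantoms, twenty
  seeds for the stochastic claims, and one phantom for the ten-point
  threshold sweep — sizes chosen to match the study conditions while
  keeping a full run in tens of seconds.

## Known limitations

* Loss of the private key is unrecoverable by design; the key region exists
  nowhere else.
* One key region per image; multiple sensitive regions would need repeated
  application or a generalization of the payload layout.
* The code block is a purpose-built symbology, not ISO/IEC 18004; a
  general-purpose QR scanner will not decode it, only this package (or a
  reimplementation of its documented layout) will.
* The carried side information assumes the protected image is transmitted
  bit-exactly (lossless formats only); any recompression breaks both the
  checksum and the embedding, intentionally.
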