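Package: roicrypt
Title: Partial Encryption of Medical Images with Reversible Key-Region Hiding
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Protects the diagnostically sensitive region of an 8-bit grayscale
    medical image while keeping the image retrievable in the open. The lesion
    ("key") region is located as the 160x160 block with maximal coefficient of
    variation, its pixels are embedded bit-exactly into high-texture blocks by
    prediction-error expansion with histogram shifting, textured blocks are
    scrambled with the Arnold cat map, and the key region is replaced by a
    2-D matrix code carrying cleartext patient metadata plus RSA-protected
    descrambling parameters. Authorized decryption inverts every stage and
    restores the original image pixel for pixel; tools for PSNR/SSIM quality
    assessment and a seeded lesion-phantom generator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    png,
    openssl
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'raster_io.R'
    'region_select.R'
    'rdh_pee.R'
    'arnold.R'
    'qr_payload.R'
    'metrics.R'
    'phantom.R'
    'pipeline.R'
    'roicrypt-package.R'
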