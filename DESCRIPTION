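Package: handspec
Title: Automated Melanin and Haemoglobin Mapping of the Hand from
    Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A fully automatic pipeline for quantifying skin chromophores
    (melanin and haemoglobin) in VNIR hyperspectral images of the dorsal
    human hand. Reads and writes ENVI-format cubes (BIL/BIP/BSQ), performs
    white-reference calibration, median filtering, min-max normalization
    and moving-average illumination flattening, locates the hand by
    rotation-criterion search, Otsu binarization and contour-minima
    fingertip landmarking, matches the detected landmarks to an
    anthropometric hand template by exhaustive displacement search,
    aggregates spectral bands into melanin and haemoglobin maps, and
    reports per-finger region statistics over a 12-area partition. A
    synthetic hand-phantom generator with analytic ground truth makes the
    whole pipeline verifiable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
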