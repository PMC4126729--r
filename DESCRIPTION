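Package: afpq
Title: Quantification of Exhaled-Aerosol Fingerprint Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for quantifying exhaled-aerosol particle patterns
    ("aerosol fingerprints") recorded on the mouth-exit plane. Turns 2-D
    particle clouds and concentration images into feature sets: box-counting
    fractal dimension (whole-image, region-of-interest, and tiled local
    grids), sliding-box lacunarity, direct-method multifractal spectra and
    generalized dimensions, directional spatial probability profiles
    (horizontal, vertical, radial, circumferential), and
    concentration-disparity maps. Includes a seeded synthetic fingerprint
    generator emulating healthy and diseased exhalation patterns plus
    analytic fractal fixtures with known dimensions, replicate aggregation
    and Kruskal-Wallis comparison across models, and an end-to-end analysis
    pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
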