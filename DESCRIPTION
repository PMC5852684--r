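Package: matcover
Title: Forest-Cover Reconstruction from Pollen Assemblages by the Modern Analog Technique
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reconstructs past forest cover from fossil pollen assemblages using
    the Modern Analog Technique (MAT). A calibration set is built by pairing
    modern pollen samples with distance-weighted satellite forest-cover values
    extracted through a two-dimensional Gaussian kernel; assemblages are scored
    into plant functional types (PFTs) before analog matching under the
    squared-chord dissimilarity; quality filters remove unreliable modern
    samples; an empirical quantile-mapping curve corrects the systematic
    under-prediction of dense forest; reconstructions are binned into 250-year
    timeslices and interpolated onto space-time grids with thin-plate splines,
    with companion error fields, regional area-average series, and Alpine-style
    elevation-band summaries. A synthetic-landscape generator with known ground
    truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
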