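Package: pupiltrack
Title: Pupil Detection and Gaze Mapping for Video-Oculography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dark-pupil video-oculography toolkit: synthetic infrared-style
    eye image generation with exact ground truth, adaptive percentile
    binarization and morphological pupil reconstruction, six pupil-center
    detection algorithms (centroid, projection function, circular and
    elliptical Hough transforms, direct least-squares ellipse fitting, and
    RANSAC ellipse fitting), biquadratic eye-to-screen gaze calibration with
    a mapping-rate quality indicator, and evaluation metrics for static
    images, on-screen cursor trajectories, dwell-based selection, and gaze
    typing error rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
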