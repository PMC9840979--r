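Package: strifr
Title: Struggle-Response Analysis for Restrained Fly Videos
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis of struggle behavior in restrained
    (thorax-glued) Drosophila from multi-fly video: blob detection with
    Otsu thresholding and morphological cleaning, fixed square regions of
    interest per fly, frame-differencing motion-energy traces with median
    and minimum-difference denoising, segmentation into activity and
    immobility epochs under a five-second immobility rule, struggle
    metrics (activity:inactivity ratio, epoch counts and durations,
    stride-two struggle speed), optogenetic before/after contrasts aligned
    to an illumination flash detected from background RGB jumps, and an
    estimation-statistics layer (Glass delta, Cohen's d, bias-corrected
    and accelerated bootstrap confidence intervals, permutation t-tests,
    effect-size matrices, delta regressions, analytic power). Includes a
    synthetic-video generator with programmed activity/immobility ground
    truth so the full pipeline is testable without real recordings.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    ggplot2,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
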