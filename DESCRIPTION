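Package: eccfit
Title: Eccentricity-Weighted Data Augmentation for Ellipse Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for least-squares ellipse fitting with an
    eccentricity-aware pre-processing step.  Implements five classical
    conic/ellipse fitters (basic algebraic least squares, direct
    ellipse-specific fitting, its numerically stable variant,
    gradient-weighted fitting, and iterative Sampson-distance
    minimisation) behind a single fitting interface, a per-point
    eccentricity measure, and a systematic-resampling augmentation
    algorithm that densifies point sets near the ends of the major axis
    before a second-pass fit.  Includes orthogonal-distance error
    evaluation, a synthetic generator for sector-restricted and occluded
    noisy arcs such as tracked root-tip trajectories, the closed-form
    theory of when a supplementary point improves an axis-aligned fit,
    and a reproducible Monte-Carlo benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
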