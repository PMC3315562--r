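Package: splinetrend
Title: Spline-Based Removal of Head-Motion Trends from Dual-Axis
    Swallowing Accelerometry Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Removes low-frequency components associated with head movements
    from dual-axis (anterior-posterior, superior-inferior) swallowing
    accelerometry signals by least-squares B-spline approximation on a coarse
    knot lattice, implemented as the classical prefilter, decimate, postfilter
    pipeline for discrete B-splines.  Includes baseline detrenders (smoothness
    priors, piecewise polynomial fitting, empirical mode decomposition), a
    synthetic dual-axis signal generator with ground truth for Monte-Carlo
    accuracy studies, MSE/NMSE evaluation experiments over SNR grids,
    variance-based swallow segmentation with CSS/NFP/NFN scoring, and
    detrended fluctuation analysis of statistical persistence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
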