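Package: illumdisc
Title: Synthetic Illumination-Discrimination Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A fully synthetic pipeline for illumination-discrimination
    psychophysics. Generates luminance-matched comparison-illuminant series
    along the Planckian locus (blue/yellow) and the orthogonal iso-CCT line
    (red/green) parametrized in CIELUV colour difference, synthesizes each
    illuminant as a spectrally smooth nonnegative combination of simulated
    LED channels, renders Mondrian surface ensembles as 31-band hyperspectral
    images, runs simulated observers through interleaved 1-up-2-down adaptive
    staircases, extracts 70.71%-correct thresholds by cumulative-Weibull
    maximum-likelihood fitting, and evaluates image differences with the
    S-CIELAB spatial colour metric.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
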