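Package: oadepth
Title: Optoacoustic Depth Profiling with a Layered-Medium Forward Model and
    IRF Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for near-field optoacoustic (photoacoustic) A-scan depth
    profiling with a thin piezoelectric film detector embedded in a layered
    probe. Provides a layer-stack acoustic model (impedances, reflection and
    transmission coefficients, times of flight, echo-path enumeration), a 1D
    staggered-grid finite-difference simulator of the pressure transient at
    the detector plane, the signal-processing chain used to recover pressure
    profiles from raw traces (10th-order polynomial pyroelectric baseline
    removal, Butterworth time-domain windowing of the instrument response
    function, 20 MHz frequency-domain Butterworth low-pass, FFT
    deconvolution), pyroelectric active-area scan maps, and a seeded
    synthetic raw-trace generator that supplies ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
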