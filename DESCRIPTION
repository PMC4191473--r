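Package: retmap
Title: Fourier Retinotopic Mapping and Visual Electrophysiology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of periodic-stimulation intrinsic-signal optical imaging
    and visual electrophysiology. Extracts the fundamental Fourier component of
    reflectance time series, removes constant bias, combines oppositely moving
    stimulus directions into absolute retinotopic maps in visual degrees, and
    scores map quality by tilt of the zero-phase line, local phase scatter and
    cortical magnification factor. Also scores visually evoked potentials
    (peak-to-trough amplitude, contralateral bias index, normalized spatial
    frequency and contrast response curves) and electroretinogram a- and
    b-waves, and provides summary-statistic t tests and a repeated-measures
    ANOVA with a linear within-subject contrast. A synthetic-data generator
    with known ground truth supports closed-loop validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
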