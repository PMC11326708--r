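Package: racetube
Title: Circadian Period and Growth Rate Analysis of Race Tube Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies circadian periods and growth rates of filamentous
    fungi (e.g. Neurospora crassa) from scanned race-tube pack images.
    Normalizes scans to a canonical greyscale frame, detects tube
    boundaries by Canny edge detection with a Hough transform and by
    vertical densitometry, extracts per-tube densitometry traces, removes
    time-mark pen artifacts, locates conidial banding peaks, and estimates
    the free-running period by four methods: linear regression on band
    spacing, the Sokolove-Bushell chi-squared periodogram, the
    Lomb-Scargle periodogram, and continuous wavelet transform ridge
    extraction. Includes a synthetic race-tube image generator with known
    ground truth, a reloadable experiment-file format, CSV/plot exports,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    png,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
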