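Package: alpcurve
Title: Lactation-Curve Modelling for Mountain-Pastured Dairy Cows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the milk-yield drop of dairy cows summered on alpine
    pastures (transhumance). Extends the Wilmink lactation curve with
    piecewise terms for the alping decline, the post-return boost and the
    post-alping slope, fitted as weighted linear regressions on per-DIM
    averaged test-day records. Includes the temperature-humidity and
    cold-stress climate indices with inverse-distance station interpolation
    and elevation lapse correction, a 14-rule quality-control cascade with
    removal accounting, tertile-based two-group factor contrasts with
    likelihood-ratio G-tests and Bonferroni correction, and a synthetic herd
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    lmtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
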