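Package: heatwind
Title: Temperature-Humidity-Dependent Wind Effects on Physiological Heat
    Strain and the UTCI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how increased wind speed shifts physiological
    heat strain across temperature-humidity conditions and to compare those
    effects with the assessment given by the Universal Thermal Climate Index
    (UTCI). Provides the UTCI operational-procedure polynomial with its
    wind-speed height conversion and angle-averaged relative air velocity,
    psychrometric wind-effect fields with zero-effect contour extraction,
    a synthetic generator for climate-chamber trial tables (heart rate,
    rectal and skin temperature, sweat rate), penalized tensor-product
    spline (GAM) estimation of wind-effect difference surfaces with
    pointwise significance, and rank-correlation plus binary classification
    metrics relating UTCI wind effects to physiological ones.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
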