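Package: canopytrait
Title: Crop Trait Monitoring from Narrow-Band Spectrometers and Hemispherical Photography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-level (UAV and ground spectrometer) monitoring of crop
    canopy traits. Implements a narrow-band vegetation index library (NDVI, WDVI,
    OSAVI, MCARI/TCARI families, CI_re, CI_g, MCARI2, REP, MTCI, PRI), inversion of
    digital hemispherical photographs for plant area index, average leaf inclination
    angle, clumping (logarithmic gap averaging) and ground cover, plot boundary
    recovery from vegetation-index maps by Canny edge detection, linear VI-to-trait
    retrieval with repeated k-fold cross-validation and confidence/prediction
    intervals, cross-sensor index intercomparison (slope discrepancy) and
    treatment-discrimination statistics based on the Bhattacharyya coefficient,
    plus solar geometry utilities and a synthetic-data generator emulating a
    strip-plot field experiment so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, jsonlite, yaml, EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
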