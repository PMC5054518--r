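Package: oxisoscape
Title: Oxygen Isotope Isoscapes and Mobility Inference by Ordinary Kriging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geostatistical modelling of skeletal phosphate oxygen isotope
    values (d18Op) over a planar survey region such as the British National
    Grid. Provides grid-reference parsing and two-point measurement
    calibration, inverse-distance spatial weights with global and local
    (Anselin) Moran's I cluster/outlier screening under false-discovery-rate
    control, second-order polynomial trend removal, empirical semivariogram
    estimation with stable-model fitting, ordinary kriging prediction and
    standard-error surfaces with cell declustering, leave-one-out
    cross-validation, and residual-based classification of candidate
    non-local individuals. A seeded synthetic-isoscape generator reproduces
    the statistical structure the analysis assumes (smooth trend, correlated
    residual field with nugget, preferential sampling, planted migrants) so
    the whole pipeline is testable without archaeological data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
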