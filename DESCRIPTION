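Package: mvctdose
Title: Imaging Dose Simulation for Megavoltage CT on Helical Tomotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the absorbed dose delivered to phantoms and organs by
    megavoltage CT (MVCT) imaging on a helical tomotherapy unit. Provides a
    commissioned single-field (400 x 4 mm) beam model built from percentage
    depth dose and off-center ratio curves, a fully synthetic analytic beam
    generator for machine-free testing, voxel phantom generators (cylindrical
    "cheese" phantom, slabs, heterogeneous inserts), discretization of helical
    and static deliveries into equally spaced beams with monitor units derived
    from irradiation time, a factorized divergent-beam dose engine with
    Siddon radiological-depth ray tracing, beam output calibration against a
    point measurement, chamber-style point-dose extraction, and organ-level
    reporting (maximum dose per fraction, totals over fractionation, percent
    of prescription, dose-volume histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
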