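Package: cottonfq
Title: Phytomer-Based Simulation of Cotton Fibre Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Daily-timestep, per-fruit simulator of cotton plant architectural
    development and fibre quality (length, strength, micronaire) driven by
    temperature and management. Plant topology is built phytomer by phytomer on
    a physiological-day clock; each fruit accumulates potential fibre quality
    along a logistic curve of its thermal age, reduced by daily temperature
    factors. Includes a synthetic weather generator tuned to site thermal sums,
    a management scenario engine (sowing date, main-stem and branch topping,
    film mulching), logistic calibration utilities and the RMSE / relative
    error goodness-of-fit metrics used in crop modelling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
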