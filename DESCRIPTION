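Package: becyr
Title: Bio-Economic Crop Yield Response Modelling for Corn and Soybeans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating bio-economic crop yield response (BECYR)
    models on county-year panels: frost-threshold growing-season detection and
    growing-degree-day accumulation from daily weather, reconstruction of a
    local monthly CO2 history from a reference station via a monthly
    fixed-effects proxy regression, panel assembly with harvest-area-weighted
    county boundary harmonisation and CPI deflation, quadratic county
    fixed-effects yield regression with cluster-robust inference, and
    derived response quantities (CO2 turning points, peak-yield moisture and
    heat levels, per-variable yield attribution). A synthetic-data module
    generates every input the pipeline consumes, with known generating
    parameters, so the full analysis is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    purrr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
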