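Package: erwsim
Title: Coupled Ecosystem Simulation of Enhanced Rock Weathering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulates enhanced rock weathering (ERW) in a vertically lumped,
    biogeochemically active soil layer coupled to a bucket water balance,
    microbially explicit soil organic carbon decomposition, nutrient budgets,
    cation exchange, and a single-canopy vegetation component. Feedstock
    mineral dissolution follows Palandri-Kharaka kinetics with a
    soil-moisture factor; the carbonate system (alkalinity, pH, dissolved
    inorganic carbon, soil CO2 efflux, pedogenic carbonate) is solved at
    10-minute sub-steps. Outputs include potential and effective carbon
    dioxide removal time series and full element conservation ledgers. A
    synthetic-forcing generator makes the whole system testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
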