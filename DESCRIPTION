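Package: c4leak
Title: Bundle-Sheath CO2 Leakiness of C4 Leaves from Coupled Gas-Exchange
    and Tunable Diode Laser Carbon Isotope Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates bundle-sheath CO2 leakiness (phi) of NADP-ME C4
    leaves continuously through photosynthetic induction from coupled
    gas-exchange logs and 10 Hz tunable diode laser (TDL) isotopologue
    streams.  Implements concentration-series calibration with drift
    correction of the TDL, online 13C photosynthetic discrimination
    (Delta13C) with its instrument-error model and exclusion rule, the
    von Caemmerer C4 biochemical inversion for leakiness assuming
    infinite mesophyll conductance, chamber washout and transport-delay
    correction, and kinetic characterisation of induction (piecewise
    fits, time constants, induction times, window means and ATP costs).
    A forward simulator generates both instrument streams from a known
    true phi(t) so the whole inversion is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
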