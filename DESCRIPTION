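Package: cvstate
Title: Mechanistic Cardiovascular State Inference from Blood Pressure Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and inverse estimation for a lumped-parameter
    model of the systemic circulation with autonomic (baroreflex and
    independent) control. Simulates hypovolemic, distributive and combined
    shock scenarios as pressure-form ordinary differential equations;
    synthesizes beat-resolved 125 Hz arterial and venous pressure waveforms;
    extracts the five bedside observables (mean arterial and venous pressure,
    heart rate, pulse pressure, and the scaled resistance-compliance product)
    at 10 Hz with validity screening; and infers fifteen hidden physiological
    parameters per 300-second window by constrained multi-start optimization,
    reporting volume-loss, vascular-tone and contractility shock indices.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
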