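Package: kvclamp
Title: Voltage-Clamp Protocol Simulation and Analysis for Kv3.3 Channel Gating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing voltage-gated Kv3.3 potassium channels from
    two-electrode voltage-clamp style recordings: construction of standard step,
    tail-current, inactivation, recovery and pulse-train protocols; a deterministic
    Hodgkin-Huxley-style oocyte simulator with bi-exponential N-type inactivation,
    extracellular-potassium-dependent gating, expression scatter, leak and noise;
    Boltzmann conductance-voltage and exponential time-constant fitting; recovery-
    from-inactivation and cumulative-inactivation quantification; Nernst and
    Goldman-Hodgkin-Katz driving-force predictions; and end-to-end experiment
    recipes comparing wild-type channels with disease-associated variants such as
    Kv3.3-E675K.
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
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
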