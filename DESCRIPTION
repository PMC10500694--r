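Package: presatr
Title: Multisite Solvent-Signal Presaturation for NMR: Shaped-Pulse
    Synthesis and Bloch-Equation Simulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design and simulation of multisite solvent-signal presaturation
    for liquid-state NMR. Builds multiple-frequency-shifted laminar shaped
    pulses from a list of solvent resonance positions, propagates nuclear
    magnetization through the pulse train with an alternating
    rotation/relaxation splitting of the Bloch equations (validated against a
    controlled-accuracy ODE integration), and computes frequency-domain
    saturation profiles, on-resonance attenuations and 50 percent-attenuation
    bandwidths, including the interference regime of close-frequency
    resonances. Includes reading and writing of peak lists and of a documented
    JCAMP-DX-like shaped-pulse file dialect, plus a small command-line front
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
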