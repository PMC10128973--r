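Package: numspin
Title: Spin-Network Simulation and Ideal-Observer Decoding of Numerosity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates open quantum spin-1/2 networks driven by transient
    local stimuli, using quantum-trajectory unravelings of the
    Gorini-Kossakowski-Sudarshan-Lindblad master equation, and decodes the
    number of stimulation events from magnetization amplitude spectra with
    an ideal-observer template classifier. Includes virtual
    two-alternative forced-choice psychophysics with Probit fits and
    Weber-fraction analysis, and classical sinusoidal control signals for
    decoder validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
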