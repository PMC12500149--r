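Package: neurocsp
Title: Computational Singular Perturbation Analysis of Brain Energy Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Kinetic model of human brain energy metabolism across neuronal,
    astrocytic, extracellular and vascular compartments (29 state variables,
    67 unidirectional reaction and transport rates), together with a
    computational singular perturbation (CSP) engine for multiscale timescale
    decomposition. Simulates an in-vivo activation protocol (presynaptic
    stimulation plus a trapezoidal cerebral blood flow response and venous
    balloon), decomposes the local dynamics into fast exhausted and slow
    active modes via Jacobian eigenanalysis, segments the response into
    periods of constant exhausted-mode count, and reports the amplitude
    participation index, timescale participation index and CSP pointer
    diagnostics that identify the reactions and metabolites controlling each
    period. Includes analytically solvable two-timescale toy systems for
    validating the decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    pracma,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
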