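Package: qtanimoto
Title: Quantum-Encoded Tanimoto Similarity with Noise and Error Mitigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Encodes classically computed Tanimoto similarity between molecular
    fingerprints into a three-qubit entangled (GHZ-like) quantum state, simulates
    the encoding circuit exactly as an 8x8 density matrix under configurable
    depolarizing noise, estimates the encoded similarity from Pauli-observable
    expectation values of measurement counts, and recovers it with exponential
    error-mitigation rescaling. Includes a Morgan-fingerprint adapter (via an
    external chemistry toolkit), a synthetic fingerprint-pair generator, noise
    sweeps over log-spaced error rates, and report export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
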