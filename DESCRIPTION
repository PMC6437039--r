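Package: platelogic
Title: Distributed Multicellular Boolean Logic on Microplates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compiles n-bit multi-output Boolean functions into microplate
    layouts of one-hot antibiotic-resistance bacterial strains, simulates
    each well's multi-strain batch growth under antibiotic-encoded binary
    inputs, and verifies that the colorimetric (yellow/blue) endpoint
    readout computes the target function. Ships the benchmark devices of
    the distributed-logic architecture (one-hot decoder arrays, a
    calculator-style digit display, a 3-bit full adder and full
    subtractor), JSON/CSV plate serialization, an ASCII plate renderer, a
    command-line interface, and Monte-Carlo analysis of readout
    reliability under biological noise including majority-vote redundancy.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
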