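Package: sonatar
Title: Read, Write and Validate SONATA Neuronal Network Circuit and Activity Files
Version: 0.1.0
Authors@R:
    person("SONATA", "Tools Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: An implementation of the SONATA data format for large-scale
    neuronal network models: circuit descriptions as HDF5 node and edge
    instance tables paired with space-separated CSV type tables, a JSON
    configuration hierarchy (primary, circuit and simulation configs with
    manifest variable substitution), and activity reports (spike trains and
    chunked N-by-M element/frame time-series matrices). Includes edge
    orderings (target-major, source-major, hybrid) with range indices for
    fast per-node edge queries, a cross-file structural validator, a
    synthetic hybrid-circuit and activity generator for self-contained
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rhdf5,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
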