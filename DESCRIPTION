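Package: boolattract
Title: Attractor Detection in Asynchronous Boolean Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects attractors (fixed states and stable cycles) of
    asynchronously updated Boolean regulatory networks by exhaustive
    enumeration of pruned subspaces of the state space. Logical functions
    follow the Thomas positive-influence parameterization and may be left
    partially specified: fixed states are then reported together with the
    constraints on the free logical parameters that realize them. Includes
    signed feedback-loop detection, a degree-constrained random benchmark
    network generator, Monte-Carlo estimation of the discontent-count
    distribution, a brute-force full-state-space oracle for small networks,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
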