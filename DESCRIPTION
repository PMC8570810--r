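Package: netctrl
Title: Structural Target Controllability of Directed Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct directed protein-protein interaction subnetworks
    around seed nodes and find small sets of input (source) nodes --
    preferentially drug-targetable ones -- that structurally control a
    prescribed set of target nodes, returning explicit control paths.
    Implements a greedy layer-by-layer matching algorithm and a genetic
    algorithm over per-target input assignments, both verified against an
    exact generic-rank (Kalman) test computed over a finite field.
    Includes seed-based subnetwork generation (first-neighbour, direct,
    and bounded-intermediary modes), random-network simulators for
    testing, edge-list/SIF/JSON input-output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grid,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
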