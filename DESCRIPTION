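Package: pathwrap
Title: Wrap-Around Randomization of Animal Movement Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Null models for distinguishing social attraction from spatial
    constraints in proximity-based animal social networks. Implements the
    wrap-around (conveyor-belt) time-shift randomization of movement
    trajectories and the classical day-shuffling ('path shuffling')
    randomization, a biased-correlated random walk agent-based simulator with
    mobile home-range centres and optional nearest-neighbour social attraction,
    proximity-based interaction detection (co-location, co-movement, and
    in-flight rules) with weighted social-network construction (counts or
    simple ratio index), and a permutation-inference harness (Z-scores,
    two-tailed empirical significance, false-positive and false-negative rate
    estimation across movement scenarios, shift ranges and sampling
    frequencies).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
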