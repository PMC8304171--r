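Package: strikentropy
Title: Entropy Analysis of Strike Positions in Racket Sports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the randomness of striking positions in badminton
    match event logs. Implements the normalized Shannon entropy of
    twelve-zone strike distributions, the transition entropy of receiving
    zones, the Clark-Evans nearest-neighbour spatial entropy of strike
    coordinates in a bounded half-court window, and a gamma-controlled
    mixture model of "four-corner" versus uniform-random striking
    strategies with Monte Carlo simulation, a closed-form entropy curve,
    and gamma fitting. Includes a seeded synthetic match generator that
    emulates elite singles stroke logs and an analysis pipeline producing
    per-match entropy splits (won/lost, leading/behind, initial/final
    phase), receiving profiles, and paired comparisons.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
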