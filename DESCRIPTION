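Package: beechoice
Title: Sequential-Sampling Models and Choice Analysis for Honey Bee Foraging Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying two-alternative accept/reject decisions of
    free-flying honey bees and of accumulator models of the underlying
    circuitry. Provides the two-protocol colour-discrimination training design
    with per-colour reward likelihoods; choice statistics (four-outcome
    response counts, Matthews correlation coefficient, signal-detection
    discriminability and decision criterion, conditional accuracy functions);
    a family of leaky stochastic accumulator models (independent race,
    cross-inhibition from command cells, learning-cell input modulation, and
    the full combined circuit) integrated by Euler-Maruyama; population-level
    simulated experiments with ablations; classification of flight-trajectory
    stimulus visits into acceptances and rejections via an exact
    one-dimensional two-means speed threshold; and synthetic choice-event and
    trajectory generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
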