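Package: aposwitch
Title: Individual-Based Simulation of Switchable Aposematic Signal Evolution
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based simulator of the evolution of permanent,
    pre-attack-switchable, and post-attack-switchable aposematic signaling in
    defended prey facing predators that acquire aversion by associative
    learning. Prey strategies are triples of discrete signal levels (none,
    low, high) assigned to the three threat states resting / approached /
    attacked; survival costs are multiplicative (switching cost, switchability
    maintenance cost, intensity-weighted signaling penalty, attack damage) and
    selection acts through clonal reproduction to a fixed carrying capacity
    with an extinction-rescue rule. Includes factorial parameter-sweep
    machinery with deterministic per-run seeding, tidy long-format results,
    and categorical phase-diagram (mini-plot / meta-plot) graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    parallel,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
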