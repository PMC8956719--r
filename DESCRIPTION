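Package: clutchfit
Title: Intergenerational Fitness of Gregarious Parasitoids from Clutch Size
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for scoring the fitness of gregarious egg parasitoids
    across two generations using the clutch size-body size-fertility
    correlation. Provides a per-offspring fertility table keyed by clutch
    size, deterministic F2-generation fertility arithmetic for arbitrary
    allocations of offspring over native and non-native hosts, exhaustive
    enumeration and optimisation of clutch-size allocations (including
    searches for same-F1/different-F2 and lower-F1/higher-F2 strategy
    pairs), expected-value host-environment scenarios and multi-generation
    population projection, a two-step estimation stage (wing-length to
    fertility regression followed by clutch-specific hypothetical
    fertilities) with normal and exact Poisson confidence intervals, and a
    seeded synthetic-data generator emulating Petri-dish parasitisation
    trials so the whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
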