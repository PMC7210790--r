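Package: dronaid
Title: Simulation and Genetic-Algorithm Siting of AED Drone Networks for
    Out-of-Hospital Cardiac Arrest Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-driven simulator for out-of-hospital cardiac arrest
    (OHCA) emergency response. Generates synthetic regions (health-trust
    polygons with population densities, residential areas, ambulance
    stations, public AEDs, candidate drone bases and no-fly zones),
    simulates probabilistic OHCA incidents allocated across trusts by
    population density with day/hour sampling from configurable
    probability mass functions, and models three responders per incident:
    a blue-light ambulance, a bystander fetching the nearest public AED
    (round trip), and an AED-carrying drone with a flight-range limit and
    no-fly-zone avoidance. A genetic algorithm over fixed-size sets of
    candidate bases minimises the mean response time; an exhaustive
    brute-force oracle validates it on small instances. Reporting covers
    diminishing-returns network sizing, time-threshold coverage,
    per-trust before/after summaries, responder mix, five-number
    summaries with a paired Wilcoxon signed-rank test, and cost and
    workload projections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    geosphere,
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
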