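Package: alcosim
Title: Agent-Based Simulation of Alcohol Consumption, Harms and Policy Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded, configurable agent-based model of individual drinking
    behaviour and alcohol-related harm in an adult population. Agents hold
    demographic attributes and a drinking category (abstainer, low, moderate,
    heavy), make daily consumption decisions through capability, opportunity
    and motivation rules situated in homes, workplaces, licensed venues
    grouped in precincts, bottle shops and peer events, and carry a
    continuous-time blood alcohol concentration computed from the Widmark
    equation. Acute harms (unintentional injury, alcohol poisoning, road
    traffic accidents, violence, exacerbations of alcohol use disorder) arise
    from a non-homogeneous Poisson process whose intensity grows non-linearly
    with blood alcohol concentration; chronic disease onsets follow
    attributable-fraction epidemiology applied to a 20-year moving average of
    consumption. A scenario layer expresses policy levers (venue closing
    times, lockouts, responsible-service refusal, treatment expansion) as
    configuration overlays, and a reporting layer computes monthly per-100,000
    incidence, replicate summary statistics and baseline-versus-scenario
    percent reductions with 95 percent margins of error, plus a calibration
    harness for tuning free parameters to target statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    igraph,
    lhs,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
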