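Package: beecology
Title: Individual-to-Colony Analysis of Honeybee Heat-Stress Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse automated-tracking data of individually
    tagged honeybees during an ambient heat stress, from raw detection
    tables to colony-level summaries. Computes ten behavioural metrics
    (nest-frame occupancy, exit distance, detection time, outside trips,
    speed, dispersion, fraction of nest visited) over 1-minute, 5-minute
    and hourly bins; infers nest exits and entries from detection gaps;
    embeds behavioural hours by principal component analysis and Ward
    hierarchical clustering; quantifies morning-to-heat-stress cluster
    transitions against an independence null; and measures the
    persistence of individual behavioural fingerprints with a vector
    correlation coefficient. A synthetic colony generator with planted
    behavioural groups and an injectable heat-stress effect makes the
    full pipeline testable without tracking hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
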