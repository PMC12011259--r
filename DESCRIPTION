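Package: forestcarbon
Title: Forest Carbon Sequestration Measurement by the Biomass Method
Version: 0.1.0
Authors@R: person("forestcarbon", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for measuring the net carbon sink of afforestation
    projects by the biomass method: stratified sampling design for
    monitoring plots (sample-size, finite-population adjustment, optimal
    allocation), per-tree biomass estimation (allometric power-law and a
    small feed-forward neural network), per-carbon-pool stock-change
    accounting to net CO2-equivalent sink, forest inventory cleaning and
    splicing, stand volume statistics, prediction-error validation, and a
    synthetic stand generator so every stage is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
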