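Package: regiosim
Title: Agent-Based Simulation of Obstetric Delivery-Care Regionalisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based microsimulation of where pregnant women deliver
    under policies that regionalise childbirth care. Synthetic cohorts of
    women choose a delivery facility through a two-step latent-class
    conditional-logit model over a road network (A* routing with
    straight-line fallback for disconnected locations); policy scenarios
    restrict delivery to caesarean-capable or high-volume emergency-care
    facilities, optionally upgrading sites chosen by greedy
    maximal-coverage siting. The pipeline reports neonatal mortality,
    utilisation shifts across facility types, travel distance,
    out-of-pocket and catastrophic expenditure, and utility decrements
    expressed as willingness-to-travel kilometres, with means and 95%
    posterior credible intervals over replicate runs.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
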