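Package: impquant
Title: Quantifying Implementation of Multi-Component Interventions in Stepped-Wedge Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores process-evaluation data from multi-component workplace
    interventions delivered in stepped-wedge cluster randomized trials.
    Deliverer logbooks and participant questionnaires are rescored onto a
    0-100 scale, combined into delivery measures (dose, content, quality,
    fidelity), receipt measures (duration-weighted participation with
    team-level representation and continuity scoring for participatory
    components, and responsiveness from satisfaction, social support and
    motivation), and chained into exposure and implementation scores at
    session, individual and organizational level. Includes stratified
    reporting by intervention component, trial step and workplace, index
    reliability (Cronbach's alpha), one-way ANOVA group comparisons, and a
    synthetic trial generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    tidyr,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
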