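Package: vaxdce
Title: Discrete-Choice Analysis of Stated COVID-19 Vaccine Acceptance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates conditional logit, panel random-parameter logit with a
    normally distributed opt-out constant, and latent-class conditional logit
    models for stated-choice vaccine acceptance data, with post-estimation
    willingness-to-pay ratios, odds ratios of opting out, posterior class
    assignment and scenario probability curves. Includes a seeded synthetic
    choice-experiment generator (design, respondent population, simulated
    choices) so the full pipeline is testable end-to-end, plus CSV/YAML I/O
    and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
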