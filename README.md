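# vaxdce

Discrete-choice analysis of stated COVID-19 vaccine acceptance.

Health economists and epidemiologists use discrete choice experiments
(DCEs) to learn, before a vaccine exists, how people would trade off its
attributes — out-of-pocket cost, effectiveness, side-effect risks, duration
of protection, who recommends it, where it was developed — against simply
not getting vaccinated. vaxdce implements the full estimation pipeline for
a two-vaccine-plus-opt-out panel DCE:

* **Conditional logit (CL)** with utilities
  `u_ijt = x_ijt'(β + Π w_i) + ε_ijt` for the vaccines and an opt-out index
  `u_iot = δ_io + w_i'γ + ε_iot` over respondent covariates.
* **Panel random-parameter logit (RPL)** with a normally distributed
  opt-out constant `δ_io ~ N(δ_o, σ_o²)` shared across a respondent's
  tasks, estimated by maximum simulated likelihood on Halton draws.
* **Latent-class conditional logit (LCL)** with `Q` preference classes and
  a multinomial-logit class-membership model, estimated by EM with
  multiple seeded starts, ranked by BIC.
* **Post-estimation**: marginal willingness to pay `ω_k = −β_k/β_cost`
  (delta-method SEs, income-group splits), odds ratios of opting out
  `exp(γ)`, posterior (Bayes) class probabilities and random class
  assignment, and scenario probability curves with crossing points.
* **A synthetic DCE generator** (level-balanced seeded design, respondent
  population from published marginals, choices drawn from the exact model
  probabilities) so every estimator is validated end-to-end by parameter
  recovery — the original survey microdata are not publicly deposited.

## Worked example

Simulate a study-sized panel from the built-in conditional-logit
coefficient set, fit, and look at the economics:

```r
library(vaxdce)

spec   <- spec_variant("cl1")                  # linear cost, fixed constant
design <- generate_design(design_config(seed = 1))
pop    <- sample_population(population_config(n_respondents = 1000, seed = 2))
truth  <- reference_parameters("cl1")
data   <- simulate_choices(design, pop, truth, "CL", spec, seed = 3)
data
#> Stated-choice dataset: 7000 tasks from 1000 respondents
#>   choice shares: A 0.283, B 0.276, optout 0.441

fit <- fit_conditional_logit(data, spec)
fit
#> CL fit: 7000 tasks, 1000 respondents
#>   loglik: -6686.2614  BIC: 13691.255  k: 36
#>   converged: TRUE  (|gradient| = 1.72e-11 )
#>        parameter     estimate           se           z            p stars
#> 1           cost -0.004213862 0.0003678076 -11.4567038 2.176411e-30   ***
#> 2  effectiveness  0.010665078 0.0010961071   9.7299603 2.246806e-22   ***
#> 3     protection  0.038933052 0.0092078390   4.2282508 2.355152e-05   ***
#> ...
```

The fitted cost coefficient is the marginal disutility of a dollar, so each
extra month of protection is worth about nine dollars to the lower-income
group (the generating value is `0.0311/0.0043 ≈ $7.2`, inside the interval):

```r
wtp(fit, "protection", "low")
#>         name group      wtp       se   ci_low ci_high significant
#> 1 protection   low 9.239279 2.325572 4.681159 13.7974        TRUE
```

Opt-out odds ratios read against 1: men and postgraduates are roughly half
as likely to refuse vaccination, ceteris paribus:

```r
head(odds_ratios(fit)[, c("name", "odds_ratio", "ci_low", "ci_high", "stars")], 5)
#>                 name odds_ratio    ci_low   ci_high stars
#> 1    optout_constant  3.0305559 2.0230528 4.5398068   ***
#> 2               male  0.5116326 0.4604841 0.5684625   ***
#> 3   household_income  0.9781851 0.9689029 0.9875563   ***
#> 4      education_bsc  0.9433415 0.8317304 1.0699299
#> 5 education_postgrad  0.5916766 0.5144982 0.6804323   ***
```

`fit_rpl()` adds the random opt-out constant, `em_fit_lcl()` fits latent
classes, `model_selection()` ranks fits by BIC, `scenario_curves()` sweeps
one attribute of vaccine A against a fixed vaccine B for a configurable
(representative) respondent, and `run_pipeline()` drives
simulate → fit → post-estimation → selection from a single YAML/JSON config
(a thin command-line wrapper lives in `inst/cli/vaxdce.R`). See the
vignette in `vignettes/vaccine-choice-modelling.Rmd` for the models,
defaults and numerical choices.

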