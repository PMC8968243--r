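---
title: "Modelling stated COVID-19 vaccine acceptance with discrete-choice methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stated COVID-19 vaccine acceptance with discrete-choice methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

vaxdce estimates how people trade off the attributes of hypothetical
COVID-19 vaccines — out-of-pocket cost, effectiveness, side-effect risks,
duration of protection, who recommends the vaccine, where it was developed —
against the option of taking no vaccine at all, from stated-choice survey
data. This vignette explains the models, the choices made where the design
was genuinely open, the synthetic data generator used to validate every
estimator, and the package's known limits.

## The choice models

Respondent $i$ faces $T$ choice tasks; in task $t$ the choice set is
$\{A, B, \text{opt out}\}$. The two vaccine alternatives carry truncated
indirect utilities linear in the encoded attribute vector $x_{ijt}$,

$$u_{ijt} = x_{ijt}'(\beta + \Pi w_i) + \varepsilon_{ijt},$$

while the opt-out alternative carries an index of respondent covariates
$w_i$ rather than vaccine attributes,

$$u_{iot} = \delta_{io} + w_i'\gamma + \varepsilon_{iot},$$

with iid type-I extreme-value shocks, so each task's choice probabilities
are a three-way softmax. Three estimators share this structure:

* **Conditional logit (CL)** — $\delta_{io} = \delta_o$ fixed. Every task is
  treated as a pseudo-individual; the panel structure is ignored.
* **Random-parameter logit (RPL)** — $\delta_{io} \sim N(\delta_o,
  \sigma_o^2)$, drawn once per respondent and shared across their tasks.
  This random effect both absorbs unobserved heterogeneity in vaccine
  hesitancy and gives the opt-out alternative its own variance (it is
  covariance-equivalent to a nested logit with a single-alternative nest).
  The likelihood integrates the product of a respondent's task
  probabilities over $\delta_{io}$; estimation is by maximum simulated
  likelihood.
* **Latent-class conditional logit (LCL)** — all preference parameters
  (including the opt-out constant, which in this specification carries no
  covariates) take one of $Q$ class-specific values; class membership
  follows a multinomial logit in respondent covariates with class 1 as the
  reference. Estimation is by EM.

Post-estimation, marginal willingness to pay for attribute $k$ is the
coefficient ratio $\omega_k = -\beta_k/\beta_{\text{cost}}$ (with the
group-specific cost coefficient $\beta_{\text{cost}} + \pi_{\text{cost}
\times \text{high}}$ for high-income respondents), opt-out covariates are
reported as odds ratios $e^\gamma$, class membership as assignment odds
relative to class 1, and fitted models feed scenario probability curves.

## Encoding and units

Attributes enter in their survey units — dollars, percentage points,
days, months, persons per 10 and per 1,000,000 — with no standardisation,
so coefficients are directly comparable across fits. Origin dummies use
Germany as base; recommender dummies use the primary-care physician.
Household income enters index functions in \$10,000 units; age in years and
BMI in kg/m² are unscaled. The free-vaccine dummy is $1[\text{cost} = 0]$
and is added *on top of* the linear cost term under
`cost_mode = "linear_plus_free"`: specification 1 (`cl1`, `rpl1`) is purely
linear, specification 2 (`cl2`, `rpl2`) adds the dummy. The default
observed-heterogeneity interactions are cost × income ≥ \$120K,
effectiveness × wave 2, and China origin × Republican. The high-income
threshold is fixed at \$120,000; income enters the vaccine utility only
through this interaction.

One covariate decision was genuinely open: Hispanic ethnicity enters the
opt-out index of the CL/RPL models but is dropped from the latent-class
membership model (`DEFAULT_CLASS_COVARIATES`), where it is not informative;
both lists are plain arguments of `model_spec()` and can be overridden.

## Numerical choices

* **Softmax** — always computed after subtracting the maximum utility;
  probabilities are strictly positive and sum to one within 1e-12.
* **Draws** — the simulated likelihood uses Halton draws in base 3 with the
  first 10 points discarded, one block of `R` draws per respondent reused
  across tasks. `R = 500` by default; parameter-recovery experiments in the
  tests use `R = 200`, which at 2,000 respondents leaves simulation noise
  well inside sampling noise.
* **Optimisation** — quasi-Newton (BFGS) on analytic gradients, started
  from zero (CL) or from the CL solution with $\sigma_o = 0.1$ (RPL),
  followed by Newton polishing with the central-difference Hessian of the
  analytic gradient until the gradient norm is below 1e-6. $\sigma_o$ is
  optimised unconstrained and reported as its absolute value (the
  likelihood is symmetric in its sign). Standard errors come from the
  inverse numerical Hessian at the optimum.
* **EM** — the E-step computes responsibilities in log space; each M-step
  runs one weighted conditional-logit problem per class (warm-started, so
  partial maximisation still yields a generalised EM with a nondecreasing
  observed-data likelihood — any decrease beyond floating-point tolerance
  raises an error) and one weighted multinomial-logit membership problem.
  Convergence at relative log-likelihood change below 1e-8, at most 2,000
  iterations, best of `n_starts` seeded random initialisations (ties go to
  the earliest start). Expected class shares below 0.5% trigger an
  empty-class warning. LCL standard errors use the numerical Hessian of the
  observed-data log-likelihood via the posterior-weighted (Fisher identity)
  score.
* **BIC** — $-2\ell + k\ln n$ with $n$ the number of *choice tasks*, the
  natural count for a model that treats each task as a pseudo-individual.
  Published BIC values for this class of survey cannot be reconciled
  without the raw data and an exact $k$/$n$ convention, so the convention
  is documented rather than tuned.
* **Quadrature** — where an expectation over the random opt-out constant is
  needed outside estimation (scenario curves, cross-checks), Gauss–Hermite
  nodes from pracma are used. With $\sigma_o \approx 3.3$ the panel
  integrand is wide and skewed: 20-node quadrature still carries an error
  near 0.2 log-likelihood units on 20 respondents, so cross-checks use
  orders large enough to be self-consistent (150+), and the tests assert
  that self-consistency before using the oracle.
* **Scenario integration** — population-average probabilities use either
  Gauss–Hermite quadrature (order 30 by default) or normal draws mapped
  from a Halton sequence (`R = 10000`), which agree to about 1e-4; plain
  pseudo-random draws are available but need far larger `R` for the same
  accuracy. A `"conditional"` mode evaluates at the mean constant
  $\delta_o$ instead, which is how hypothetical-individual narratives are
  usually plotted. Crossing points (e.g. where $P(A)$ meets the opt-out
  probability) are located by linear interpolation on a 200-point grid.

## The synthetic-data generator

No microdata are distributed with surveys of this kind, so the package
ships a generator that emulates the study design end-to-end and makes every
estimator testable:

* **Design** — 24 two-alternative cards over the printed attribute levels
  (cost \$0/50/100/175; effectiveness 20–80%; incubation 7/14/21 days;
  protection 3/6/12 months; mild side effects 1/3/5 per 10; severe 1/10/100
  per 1,000,000; recommender PCP/CDC/WHO/Media; origin
  Germany/USA/UK/China; introduced 3/6 months), each respondent answering a
  simple random subset of 7. The published design was Bayesian-efficient;
  the generator substitutes a seeded, level-balanced random design, because
  design efficiency affects estimator precision rather than correctness and
  no priors or candidate set are available. Identical A/B cards are
  repaired by re-drawing one attribute.
* **Population** — 2,723 respondents by default, covariates drawn
  independently from published sample marginals (male 44.95%, bachelor
  22.29%, postgraduate 17.74%, Black 13.51%, Hispanic 12.45%, Asian 4.19%,
  Democrat 42.09%, Republican 29.93% — drawn jointly so the two are
  exclusive —, flu shot 34.52%, against vaccination 5.40%, no insurance
  13.56%, tested 22.33%, had COVID-19 4.11%, full-time 48.37%, wave-2 share
  1049/2723). Age follows the generation-band mixture
  (49.50/28.68/19.24/2.58% across millennial/Gen-X/boomer/older), income a
  log-normal with median \$45,000 (sdlog 0.8, giving a mean near \$62,000
  and roughly a tenth of the sample above the \$120K threshold), BMI a
  normal(31, 6²) truncated at 15. Marginals not published — religion
  extremely important (35%), an over-65 household member (15%), underlying
  condition (40%) — are set once to plausible US survey values and exposed
  as configuration. Only marginals are known, so covariates are
  independent: real attitude correlations (e.g. party × vaccine attitudes)
  are *not* emulated, which is exactly why recovery tests validate the
  estimators, not the sociology.
* **Choices** — drawn categorically from the exact closed-form probability
  triple (equivalent in distribution to adding Gumbel shocks, and cheaper),
  with the RPL constant drawn once per respondent and the LCL class drawn
  from the membership logit. The generating truth is attached to the
  dataset for recovery audits.
* **Truth defaults** — `reference_parameters()` and
  `reference_lcl_parameters()` carry full coefficient sets with realistic
  magnitudes and signs for US vaccine acceptance (negative cost,
  effectiveness and protection positive, a strong positive opt-out shift
  for vaccination opponents, opt-out dispersion near 3.3), so simulations
  reproduce the qualitative economics of the application: roughly
  two-thirds to 70% of tasks end in a vaccine being chosen, and opt-out
  behaviour is strongly covariate-driven.

## What the tests show — and what they cannot

Passing recovery tests demonstrate that the estimators find the parameters
of data generated by their own model at the study's scale (2,000×7 tasks,
all parameters within 3 standard errors over replicates), that the
simulated likelihood matches an independent quadrature evaluation to 1e-4,
that EM ascends monotonically and collapses to the conditional logit at
$Q = 1$, and that the simulator's choice shares match analytic
probabilities at 50,000 tasks. They cannot certify behaviour on real survey
data: attribute non-attendance, straight-lining, correlated covariates and
design endogeneity are all outside the generator. Problem sizes in the test
suite (e.g. `R = 200` draws, 3 replicates, 600-respondent latent-class
runs, 40-replicate coverage checks at 500 respondents) were chosen as the
smallest scales at which the checked properties are statistically sharp.

## Known limitations

* Only the opt-out constant is random; there are no continuous random
  coefficients on vaccine attributes, no nested-logit estimator and no
  Bayesian estimation.
* WTP is reported as marginal coefficient ratios with delta-method
  standard errors; no compensating-variation or logsum welfare aggregation.
* The latent-class likelihood is non-concave: EM from multiple starts
  mitigates but cannot rule out local optima, and models with many classes
  may legitimately fail to converge.
* Scenario curves for hypothetical individuals depend on attribute levels
  (origin, recommender) that published scenario narratives leave
  unspecified; the defaults use the base levels and are configurable, so
  such curves reproduce published figures qualitatively, not numerically.
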