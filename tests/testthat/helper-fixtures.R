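# Shared fixtures: tiny profiles, respondents, random tasks and datasets
# built in code at test time.

base_profile <- function(...) {
  args <- utils::modifyList(
    list(cost = 0, effectiveness = 80, incubation = 7, protection = 12,
         mild = 1, severe = 1, recommender = "PCP", origin = "Germany",
         introduced = 6),
    list(...))
  do.call(vaccine_profile, args)
}

# A random profile drawn from the experimental level sets (uses the current
# RNG stream; wrap in set.seed at the call site).
random_profile <- function() {
  lv <- vaxdce:::VACCINE_LEVELS
  pick <- function(x) x[sample.int(length(x), 1L)]
  vaccine_profile(pick(lv$cost), pick(lv$effectiveness), pick(lv$incubation),
                  pick(lv$protection), pick(lv$mild), pick(lv$severe),
                  pick(lv$recommender), pick(lv$origin), pick(lv$introduced))
}

random_respondent <- function(id = 1L) {
  respondent(id = id,
             male = rbinom(1, 1, 0.5), household_income = exp(rnorm(1, log(5e4), 0.6)),
             age = round(runif(1, 20, 80)), bmi = runif(1, 18, 45),
             black = rbinom(1, 1, 0.2), republican = rbinom(1, 1, 0.3),
             against_vaccination = rbinom(1, 1, 0.1),
             flu_shot = rbinom(1, 1, 0.4), wave2 = rbinom(1, 1, 0.4))
}

random_parameters <- function(spec) {
  an <- vaxdce:::attribute_column_names(spec)
  # coefficient scales matched to attribute units so utilities stay O(1)
  unit_sd <- c(free = 0.5, cost = 0.005, effectiveness = 0.01,
               protection = 0.05, incubation = 0.02, severe = 0.003,
               mild = 0.05, introduced = 0.05)
  sd <- ifelse(an %in% names(unit_sd), unit_sd[an], 0.3)
  parameters(
    beta = stats::setNames(rnorm(length(an), 0, sd), an),
    pi = stats::setNames(rnorm(length(spec$interactions), 0, 0.01),
                         vaxdce:::interaction_column_names(spec)),
    delta_o = rnorm(1, 0, 1), sigma_o = 0,
    gamma = stats::setNames(rnorm(length(spec$optout_covariates), 0, 0.1),
                            spec$optout_covariates))
}

# Small simulated panel for estimator tests.
small_dataset <- function(n_resp = 150L, model = "cl1", seed = 7L,
                          kind = if (grepl("rpl", model)) "RPL" else "CL") {
  spec <- spec_variant(model)
  simulate_choices(generate_design(design_config(seed = seed)),
                   sample_population(population_config(n_respondents = n_resp,
                                                       seed = seed + 1L)),
                   reference_parameters(model), kind, spec, seed = seed + 2L)
}

# Long-format CSV text for 2 respondents x 7 tasks, written row by row
# (independent of write_choice_data).
fixture_csv_text <- function() {
  header <- paste("resp_id,task,alt,chosen,cost,effectiveness,incubation,",
                  "protection,mild,severe,recommender,origin,introduced,",
                  "male,household_income,age,bmi,wave2", sep = "")
  costs <- c(0, 50, 100, 175, 0, 50, 100)
  effs <- c(20, 40, 60, 80, 20, 40, 60)
  rows <- character(0)
  for (r in 1:2) {
    cov <- sprintf("%d,%d,%d,%d,%d", r - 1L, 40000 + 30000 * r, 30 + 10 * r,
                   25 + 3 * r, r - 1L)
    for (t in 1:7) {
      chosen <- c("A", "B", "optout")[1L + (t + r) %% 3L]
      rows <- c(rows,
        sprintf("%d,%d,A,%d,%d,%d,7,12,1,1,PCP,Germany,6,%s", r, t,
                as.integer(chosen == "A"), costs[t], effs[t], cov),
        sprintf("%d,%d,B,%d,%d,%d,14,6,3,10,CDC,USA,3,%s", r, t,
                as.integer(chosen == "B"), costs[8L - t], effs[8L - t], cov),
        sprintf("%d,%d,optout,%d,,,,,,,,,,%s", r, t,
                as.integer(chosen == "optout"), cov))
    }
  }
  c(header, rows)
}
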