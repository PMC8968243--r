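# Synthetic discrete-choice experiment generator: design, respondent
# population, simulated choices and parameter-recovery harness.

#' Design configuration
#'
#' Attribute levels default to the nine-attribute vaccine experiment: cost
#' {0, 50, 100, 175} US$, effectiveness {20, 40, 60, 80} \%, incubation
#' {7, 14, 21} days, protection {3, 6, 12} months, mild side effects
#' {1, 3, 5} per 10, severe side effects {1, 10, 100} per 1,000,000,
#' recommender {PCP, CDC, WHO, Media}, origin {Germany, USA, UK, China},
#' introduced {3, 6} months; 24 scenarios of which each respondent answers a
#' random subset of 7.
#'
#' @param levels named list of attribute levels.
#' @param n_scenarios number of two-alternative choice cards.
#' @param tasks_per_respondent cards per respondent (<= n_scenarios).
#' @param seed integer seed.
#' @return list of class \code{design_config}.
#' @export
design_config <- function(levels = VACCINE_LEVELS, n_scenarios = 24L,
                          tasks_per_respondent = 7L, seed = 1L) {
  if (tasks_per_respondent > n_scenarios) {
    stop("tasks_per_respondent must be <= n_scenarios")
  }
  if (any(vapply(levels, length, 0L) < 2L)) {
    stop("every attribute needs at least 2 levels")
  }
  structure(list(levels = levels, n_scenarios = as.integer(n_scenarios),
                 tasks_per_respondent = as.integer(tasks_per_respondent),
                 seed = as.integer(seed)),
            class = "design_config")
}

#' Generate a seeded, level-balanced random design
#'
#' Each of the \code{n_scenarios} cards pairs two vaccine profiles whose
#' attributes are drawn from near-balanced permutations of the level sets
#' (each level appears equally often across the 2 x n_scenarios profiles, up
#' to remainder). Cards pairing two identical profiles are repaired by
#' re-drawing one attribute of alternative B.
#'
#' @param config a \code{\link{design_config}}.
#' @return data.frame with \code{card} and prefixed attribute columns
#'   \code{a_*}, \code{b_*}.
#' @export
generate_design <- function(config = design_config()) {
  n_prof <- 2L * config$n_scenarios
  withr_seed(config$seed, {
    prof <- lapply(config$levels, function(lv) {
      sample(rep(lv, length.out = n_prof))
    })
    prof <- as.data.frame(prof, stringsAsFactors = FALSE)
    a <- prof[seq_len(config$n_scenarios), , drop = FALSE]
    b <- prof[config$n_scenarios + seq_len(config$n_scenarios), , drop = FALSE]
    same <- which(rowSums(a != b) == 0L)
    for (i in same) {
      # flip one attribute of B to break the tie
      att <- names(config$levels)[sample.int(length(config$levels), 1L)]
      alt <- setdiff(config$levels[[att]], b[i, att])
      b[i, att] <- alt[sample.int(length(alt), 1L)]
    }
    names(a) <- paste0("a_", names(config$levels))
    names(b) <- paste0("b_", names(config$levels))
    cbind(data.frame(card = seq_len(config$n_scenarios)), a, b)
  })
}

#' Population configuration
#'
#' Marginal rates of the binary respondent covariates default to the emulated
#' survey sample: e.g. male 44.95\%, bachelor degree 22.29\%, postgraduate
#' 17.74\%, Black 13.51\%, Hispanic 12.45\%, Asian 4.19\%, Democrat 42.09\%,
#' Republican 29.93\%, flu shot 34.52\%, against vaccination 5.40\%, no
#' insurance 13.56\%, tested 22.33\%, had COVID-19 4.11\%, full-time worker
#' 48.37\%, wave-2 share 1049/2723. Age is drawn from a generation mixture
#' (millennial/Gen-X/boomer/older shares 49.50/28.68/19.24/2.58\%), income
#' from a log-normal with median $45,000, BMI from N(31, 6^2) truncated at
#' 15. Covariates are sampled independently (only marginals are known).
#'
#' @param n_respondents population size (default 2,723).
#' @param marginals named list overriding the Bernoulli marginals.
#' @param income_meanlog,income_sdlog log-normal income parameters.
#' @param bmi_mean,bmi_sd,bmi_min truncated-normal BMI parameters.
#' @param seed integer seed.
#' @return list of class \code{population_config}.
#' @export
population_config <- function(n_respondents = 2723L, marginals = list(),
                              income_meanlog = log(45000),
                              income_sdlog = 0.80,
                              bmi_mean = 31, bmi_sd = 6, bmi_min = 15,
                              seed = 1L) {
  defaults <- list(
    male = 0.4495, education_bsc = 0.2229, education_postgrad = 0.1774,
    black = 0.1351, hispanic = 0.1245, asian = 0.0419,
    religion_extreme = 0.35, democrat = 0.4209, republican = 0.2993,
    tested_covid = 0.2233, had_covid = 0.0411, no_insurance = 0.1356,
    flu_shot = 0.3452, against_vaccination = 0.0540,
    older65_household = 0.15, underlying_condition = 0.40,
    works_fulltime = 0.4837, wave2 = 1049 / 2723
  )
  m <- utils::modifyList(defaults, marginals)
  if (any(unlist(m) < 0 | unlist(m) > 1)) stop("marginals must be in [0, 1]")
  if (n_respondents < 1L) stop("n_respondents must be >= 1")
  structure(list(n_respondents = as.integer(n_respondents), marginals = m,
                 income_meanlog = income_meanlog, income_sdlog = income_sdlog,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_min = bmi_min,
                 seed = as.integer(seed)),
            class = "population_config")
}

# Generation age bands (years at survey time).
AGE_BANDS <- list(millennial = c(24, 39), genx = c(40, 55),
                  boomer = c(56, 74), older = c(75, 90))
AGE_SHARES <- c(millennial = 0.4950, genx = 0.2868, boomer = 0.1924,
                older = 0.0258)

#' Sample a synthetic respondent population
#'
#' Independent seeded draws per covariate: Bernoulli for the binary flags
#' (Democrat/Republican drawn jointly so they are mutually exclusive), the
#' generation-band mixture for age, log-normal income (with
#' \code{high_income = 1[income >= $120,000]} derived), truncated-normal BMI.
#'
#' @param config a \code{\link{population_config}}.
#' @return data.frame with \code{resp_id} and all respondent covariates.
#' @export
sample_population <- function(config = population_config()) {
  n <- config$n_respondents
  m <- config$marginals
  withr_seed(config$seed, {
    bern <- function(p) stats::rbinom(n, 1L, p)
    party <- sample(c("democrat", "republican", "other"), n, replace = TRUE,
                    prob = c(m$democrat, m$republican,
                             max(0, 1 - m$democrat - m$republican)))
    band <- sample(names(AGE_SHARES), n, replace = TRUE,
                   prob = AGE_SHARES / sum(AGE_SHARES))
    lo <- vapply(AGE_BANDS, `[`, 0, 1)[band]
    hi <- vapply(AGE_BANDS, `[`, 0, 2)[band]
    age <- round(stats::runif(n, lo, hi))
    income <- stats::rlnorm(n, config$income_meanlog, config$income_sdlog)
    bmi <- pmax(config$bmi_min,
                stats::rnorm(n, config$bmi_mean, config$bmi_sd))
    data.frame(
      resp_id = seq_len(n),
      male = bern(m$male),
      household_income = round(income),
      high_income = as.numeric(round(income) >= 120000),
      education_bsc = bern(m$education_bsc),
      education_postgrad = bern(m$education_postgrad),
      age = age,
      black = bern(m$black),
      hispanic = bern(m$hispanic),
      asian = bern(m$asian),
      religion_extreme = bern(m$religion_extreme),
      democrat = as.numeric(party == "democrat"),
      republican = as.numeric(party == "republican"),
      tested_covid = bern(m$tested_covid),
      had_covid = bern(m$had_covid),
      no_insurance = bern(m$no_insurance),
      flu_shot = bern(m$flu_shot),
      against_vaccination = bern(m$against_vaccination),
      older65_household = bern(m$older65_household),
      bmi = bmi,
      underlying_condition = bern(m$underlying_condition),
      works_fulltime = bern(m$works_fulltime),
      wave2 = bern(m$wave2)
    )
  })
}

#' Built-in coefficient sets for the four fixed/random-constant model variants
#'
#' Returns a full \code{\link{parameters}} object with realistic preference,
#' heterogeneity and opt-out coefficients for a US COVID-19 vaccine
#' acceptance experiment. These sets are the simulator's default truth and
#' the inputs of the worked post-estimation examples: \code{"cl1"}/\code{"rpl1"}
#' use a purely linear cost, \code{"cl2"}/\code{"rpl2"} add the free-vaccine
#' dummy; the \code{rpl} variants have a random opt-out constant
#' (sd about 3.3).
#'
#' @param model one of \code{"cl1"}, \code{"rpl1"}, \code{"cl2"}, \code{"rpl2"}.
#' @return A \code{\link{parameters}} object consistent with
#'   \code{\link{spec_variant}(model)}.
#' @export
reference_parameters <- function(model = c("cl1", "rpl1", "cl2", "rpl2")) {
  model <- match.arg(model)
  attr_names <- c("cost", "effectiveness", "protection", "incubation",
                  "severe", "mild", "introduced",
                  "origin_USA", "origin_UK", "origin_China",
                  "rec_Media", "rec_CDC", "rec_WHO")
  gamma_names <- DEFAULT_OPTOUT_COVARIATES
  sets <- list(
    cl1 = list(
      beta = c(-0.0043, 0.0102, 0.0311, -0.0120, -0.0024, -0.0355, 0.0340,
               0.2687, 0.1587, -0.3132, -0.3864, -0.0286, -0.0648),
      pi = c(0.0024, 0.0030, -0.1629), delta = 1.0540, sigma = 0,
      gamma = c(-0.6604, -0.0172, -0.1492, -0.6764, 0.0257, 0.3006, -0.0123,
                0.0833, -0.1637, -0.5340, -0.1395, -0.3353, 0.1962, -0.5152,
                1.7706, -0.2380, -0.0095, -0.3240, -0.4177)),
    rpl1 = list(
      beta = c(-0.0047, 0.0111, 0.0319, -0.0111, -0.0027, -0.0515, 0.0282,
               0.4327, 0.2527, -0.3046, -0.5599, -0.0415, -0.2166),
      pi = c(0.0024, 0.0022, -0.2017), delta = 0.6720, sigma = 3.2605,
      gamma = c(-1.4286, -0.0557, -0.3383, -1.5117, 0.0571, 0.7639, 0.0445,
                0.3388, -0.4939, -1.1452, -0.3627, -0.2013, 0.5062, -1.0224,
                4.1637, -0.4946, -0.0200, -0.6834, -0.9344)),
    cl2 = list(
      free = 0.4116,
      beta = c(-0.0030, 0.0110, 0.0319, -0.0078, -0.0026, -0.0486, 0.0497,
               0.3105, 0.1900, -0.1938, -0.4618, -0.0471, -0.1401),
      pi = c(0.0024, 0.0030, -0.1628), delta = 0.7983, sigma = 0,
      gamma = c(-0.6611, -0.0173, -0.1467, -0.6765, 0.0257, 0.3026, -0.0103,
                0.0797, -0.1631, -0.5356, -0.1394, -0.3394, 0.1989, -0.5164,
                1.7707, -0.2380, -0.0095, -0.3229, -0.4197)),
    rpl2 = list(
      free = 0.5126,
      beta = c(-0.0030, 0.0122, 0.0331, -0.0056, -0.0029, -0.0623, 0.0459,
               0.4721, 0.3350, -0.1291, -0.6660, -0.1476, -0.3281),
      pi = c(0.0024, 0.0022, -0.2051), delta = 0.3572, sigma = 3.2693,
      gamma = c(-1.4326, -0.0559, -0.3345, -1.5143, 0.0573, 0.7665, 0.0462,
                0.3339, -0.4938, -1.1516, -0.3637, -0.2049, 0.5111, -1.0262,
                4.1708, -0.4951, -0.0200, -0.6832, -0.9382))
  )
  s <- sets[[model]]
  beta <- stats::setNames(s$beta, attr_names)
  if (!is.null(s$free)) beta <- c(free = s$free, beta)
  parameters(
    beta = beta,
    pi = stats::setNames(s$pi, c("cost_x_high_income", "effectiveness_x_wave2",
                                 "origin_China_x_republican")),
    delta_o = s$delta, sigma_o = s$sigma,
    gamma = stats::setNames(s$gamma, gamma_names),
    spec = spec_variant(model)
  )
}

#' Built-in three-class latent-class coefficient set
#'
#' Default truth for latent-class simulations: three preference classes (an
#' enthusiastic-but-cost-insensitive class with a strongly positive opt-out
#' constant, a cost-sensitive middle class, and a large vaccine-accepting
#' class with a strongly negative opt-out constant) plus a multinomial-logit
#' class-membership model over the respondent covariates.
#'
#' @return list with \code{class_params} (per class: \code{beta_pi} named
#'   vector and \code{delta_o}), \code{class_gamma} (matrix, classes 2..Q by
#'   constant + covariates), \code{class_covariates}, \code{spec}.
#' @export
reference_lcl_parameters <- function() {
  spec <- spec_variant("lcl3")
  bn <- c(attribute_column_names(spec), interaction_column_names(spec))
  mk <- function(v, delta) list(beta_pi = stats::setNames(v, bn), delta_o = delta)
  cp <- list(
    mk(c(0.6442, -0.0032, 0.0181, 0.1457, -0.0018, -0.0063, -0.0829, 0.1063,
         0.6132, 0.4724, 0.0906, -0.6104, -0.5464, -1.4917,
         0.0045, 0.0073, -0.6470), 5.5959),
    mk(c(0.1848, -0.0074, 0.0217, 0.0587, -0.0173, -0.0053, -0.0761, 0.0463,
         0.6284, 0.2328, -0.6744, -0.7302, 0.0455, -0.1555,
         0.0005, 0.0022, -0.3443), 1.6116),
    mk(c(0.6492, -0.0011, 0.0098, 0.0228, -0.0016, -0.0020, -0.0434, 0.0504,
         0.2927, 0.3436, 0.0478, -0.5711, -0.1903, -0.2911,
         0.0025, 0.0013, -0.0612), -2.8583)
  )
  cg <- rbind(
    class2 = c(-0.3326, 0.5586, 0.0180, 0.1750, 0.4588, -0.0068, -0.0432,
               0.3971, -0.5129, 0.4294, 0.4021, 0.9076, -0.3106, 0.8060,
               -1.7113, 0.2735, 0.0045, 0.4914, 0.0959),
    class3 = c(0.1184, 1.0934, 0.0398, 0.2049, 1.1254, -0.0408, -0.4359,
               0.0423, 0.1798, 0.8728, 0.3170, 0.9269, -0.2865, 0.9930,
               -2.4752, 0.3519, 0.0159, 0.6363, 0.6028)
  )
  colnames(cg) <- c("constant", DEFAULT_CLASS_COVARIATES)
  list(class_params = cp, class_gamma = cg,
       class_covariates = DEFAULT_CLASS_COVARIATES, spec = spec)
}

#' Model-specification shortcuts for the standard variants
#'
#' \code{"cl1"}: linear cost, fixed opt-out constant. \code{"cl2"}: adds the
#' free-vaccine dummy. \code{"rpl1"}, \code{"rpl2"}: same with a random
#' opt-out constant. \code{"lcl2"}, \code{"lcl3"}: latent-class variants
#' (free-vaccine dummy, 2 or 3 classes).
#'
#' @param name variant name.
#' @return A \code{\link{model_spec}}.
#' @export
spec_variant <- function(name = c("cl1", "cl2", "rpl1", "rpl2", "lcl2", "lcl3")) {
  name <- match.arg(name)
  switch(name,
    cl1 = model_spec("linear"),
    cl2 = model_spec("linear_plus_free"),
    rpl1 = model_spec("linear", optout_random = TRUE),
    rpl2 = model_spec("linear_plus_free", optout_random = TRUE),
    lcl2 = model_spec("linear_plus_free", n_classes = 2L),
    lcl3 = model_spec("linear_plus_free", n_classes = 3L)
  )
}

#' Simulate panel choices from a design and a population
#'
#' Each respondent answers \code{tasks_per_respondent} randomly assigned
#' cards. Utilities follow the requested data-generating process: fixed
#' conditional logit (\code{"CL"}), random opt-out constant drawn once per
#' respondent and shared across tasks (\code{"RPL"}), or a latent class drawn
#' per respondent from the membership logit (\code{"LCL"}). Choices are drawn
#' categorically from the exact closed-form probability triple (equivalent in
#' distribution to adding Gumbel shocks, and cheaper). The generating truth
#' is attached as \code{attr(, "truth")} for recovery audits.
#'
#' @param design data.frame from \code{\link{generate_design}}.
#' @param respondents data.frame from \code{\link{sample_population}}.
#' @param true_params a \code{\link{parameters}} object (CL/RPL) or the list
#'   layout of \code{\link{reference_lcl_parameters}} (LCL).
#' @param model_kind \code{"CL"}, \code{"RPL"} or \code{"LCL"}.
#' @param spec the \code{\link{model_spec}} the parameters refer to.
#' @param seed integer seed.
#' @param tasks_per_respondent cards per respondent (default 7).
#' @return A \code{\link{dce_data}} with truth attached.
#' @export
simulate_choices <- function(design, respondents, true_params,
                             model_kind = c("CL", "RPL", "LCL"), spec,
                             seed = 1L, tasks_per_respondent = 7L) {
  model_kind <- match.arg(model_kind)
  n <- nrow(respondents)
  n_cards <- nrow(design)
  if (tasks_per_respondent > n_cards) stop("tasks_per_respondent exceeds cards")
  withr_seed(seed, {
    cards <- unlist(lapply(seq_len(n), function(i) {
      sample.int(n_cards, tasks_per_respondent)
    }))
    tasks <- design[cards, setdiff(names(design), "card"), drop = FALSE]
    tasks <- cbind(data.frame(resp_id = rep(respondents$resp_id,
                                            each = tasks_per_respondent),
                              task_index = rep(seq_len(tasks_per_respondent), n),
                              chosen = "A", stringsAsFactors = FALSE),
                   tasks)
    rownames(tasks) <- NULL
    data <- dce_data(tasks, respondents)
    truth <- list(model_kind = model_kind, params = true_params, seed = seed)
    if (model_kind == "LCL") {
      mm <- build_model_matrices(data, spec, optout_covariates = character(0))
      WR1 <- cbind(1, vapply(stats::setNames(true_params$class_covariates,
                                             true_params$class_covariates),
                             function(nm) covariate_scaled(respondents, nm),
                             numeric(n)))
      pim <- exp(membership_logprob(true_params$class_gamma, WR1))
      cls <- vapply(seq_len(n), function(i) {
        sample.int(ncol(pim), 1L, prob = pim[i, ])
      }, 0L)
      truth$class <- cls
      uA <- uB <- uO <- numeric(nrow(tasks))
      for (q in seq_along(true_params$class_params)) {
        sel <- cls[mm$resp] == q
        cp <- true_params$class_params[[q]]
        uA[sel] <- drop(mm$XA[sel, , drop = FALSE] %*% cp$beta_pi)
        uB[sel] <- drop(mm$XB[sel, , drop = FALSE] %*% cp$beta_pi)
        uO[sel] <- cp$delta_o
      }
    } else {
      validate_parameters(true_params, spec)
      mm <- build_model_matrices(data, spec)
      bp <- c(true_params$beta, true_params$pi)
      uA <- drop(mm$XA %*% bp)
      uB <- drop(mm$XB %*% bp)
      delta_i <- rep(true_params$delta_o, n)
      if (model_kind == "RPL") {
        if (true_params$sigma_o < 0) stop("sigma_o must be >= 0")
        delta_i <- delta_i + true_params$sigma_o * stats::rnorm(n)
        truth$delta_i <- delta_i
      }
      uO <- delta_i[mm$resp] + drop(mm$W %*% true_params$gamma)
    }
    m <- pmax(uA, uB, uO)
    eA <- exp(uA - m); eB <- exp(uB - m); eO <- exp(uO - m)
    den <- eA + eB + eO
    u <- stats::runif(nrow(tasks))
    pick <- ifelse(u < eA / den, "A",
                   ifelse(u < (eA + eB) / den, "B", "optout"))
    data$tasks$chosen <- pick
    attr(data, "truth") <- truth
    data
  })
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates a design, population and simulated choices, fits the
#' requested estimator, and summarises per-parameter recovery: mean bias,
#' RMSE, empirical SE of the estimates, and 95\% CI coverage. Estimator
#' failures on a replicate are recorded, not fatal.
#'
#' @param dcfg a \code{\link{design_config}}.
#' @param pcfg a \code{\link{population_config}}.
#' @param true_params truth (see \code{\link{simulate_choices}}).
#' @param model_kind \code{"CL"} or \code{"RPL"}.
#' @param spec the \code{\link{model_spec}}.
#' @param n_replicates number of replicates (>= 1).
#' @param seed base seed; replicate r uses seed + r offsets.
#' @param fit_options options passed to the fitter (e.g. \code{R} draws).
#' @return list with \code{summary} (data.frame: parameter, truth, mean_est,
#'   bias, rmse, empirical_se, coverage, n_ok) and \code{failures}.
#' @export
recovery_experiment <- function(dcfg, pcfg, true_params,
                                model_kind = c("CL", "RPL"), spec,
                                n_replicates = 3L, seed = 1L,
                                fit_options = list()) {
  model_kind <- match.arg(model_kind)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  truth <- c(true_params$beta, true_params$pi,
             optout_constant = true_params$delta_o,
             if (model_kind == "RPL") c(optout_sd = true_params$sigma_o),
             true_params$gamma)
  ests <- ses <- list()
  failures <- character(0)
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      d <- generate_design(design_config(dcfg$levels, dcfg$n_scenarios,
                                         dcfg$tasks_per_respondent,
                                         seed = dcfg$seed + 131L * r))
      p <- sample_population(population_config(
        pcfg$n_respondents, pcfg$marginals,
        income_meanlog = pcfg$income_meanlog, income_sdlog = pcfg$income_sdlog,
        bmi_mean = pcfg$bmi_mean, bmi_sd = pcfg$bmi_sd, bmi_min = pcfg$bmi_min,
        seed = pcfg$seed + 257L * r))
      dat <- simulate_choices(d, p, true_params, model_kind, spec,
                              seed = seed + 389L * r,
                              tasks_per_respondent = dcfg$tasks_per_respondent)
      fit <- if (model_kind == "CL") {
        fit_conditional_logit(dat, spec, fit_options)
      } else {
        fit_rpl(dat, spec, options = c(fit_options, list(seed = seed + r)))
      }
      list(est = fit$estimate, se = fit$se)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("replicate ", r, ": ", conditionMessage(res)))
    } else {
      ests[[length(ests) + 1L]] <- res$est
      ses[[length(ses) + 1L]] <- res$se
    }
  }
  if (!length(ests)) stop("all replicates failed: ", paste(failures, collapse = "; "))
  E <- do.call(rbind, ests)
  S <- do.call(rbind, ses)
  tr <- unname(truth)
  cover <- colMeans(abs(sweep(E, 2L, tr)) <= 1.96 * S)
  summary <- data.frame(
    parameter = colnames(E), truth = tr,
    mean_est = colMeans(E),
    bias = colMeans(E) - tr,
    rmse = sqrt(colMeans(sweep(E, 2L, tr)^2)),
    empirical_se = apply(E, 2L, stats::sd),
    coverage = cover, n_ok = nrow(E),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(summary = summary, failures = failures)
}
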