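test_that("the random design is seeded, level-balanced and has no clone cards", {
  cfg <- design_config(seed = 5)
  des <- generate_design(cfg)
  expect_equal(nrow(des), 24L)
  expect_identical(des, generate_design(design_config(seed = 5)))
  expect_false(identical(des, generate_design(design_config(seed = 6))))

  lv <- vaxdce:::VACCINE_LEVELS
  for (a in names(lv)) {
    vals <- c(des[[paste0("a_", a)]], des[[paste0("b_", a)]])
    expect_true(all(vals %in% lv[[a]]))
    # near-exact balance: 48 profiles spread over the level set, with at most
    # one displaced by the identical-pair repair
    counts <- table(factor(vals, levels = lv[[a]]))
    expect_true(all(abs(counts - 48 / length(lv[[a]])) <= 1))
  }
  attr_cols <- paste0("a_", names(lv))
  same <- rowSums(des[attr_cols] != des[sub("^a_", "b_", attr_cols)]) == 0
  expect_false(any(same))

  expect_error(design_config(tasks_per_respondent = 30), "<=")
  expect_error(design_config(levels = list(cost = 1)), "2 levels")
})

test_that("the synthetic population matches its configured marginals", {
  pop <- sample_population(population_config(n_respondents = 100000, seed = 8))
  p <- 0.4495
  expect_lt(abs(mean(pop$male) - p), 3 * sqrt(p * (1 - p) / 1e5))
  expect_lt(abs(mean(pop$against_vaccination) - 0.054),
            3 * sqrt(0.054 * 0.946 / 1e5))
  expect_true(all(pop$high_income == (pop$household_income >= 120000)))
  expect_false(any(pop$democrat & pop$republican))
  expect_true(all(pop$bmi >= 15) && all(pop$age > 0))

  # a zero marginal silences the covariate entirely
  pop0 <- sample_population(population_config(100, list(flu_shot = 0), seed = 1))
  expect_true(all(pop0$flu_shot == 0))

  expect_identical(sample_population(population_config(500, seed = 3)),
                   sample_population(population_config(500, seed = 3)))
  expect_error(population_config(marginals = list(male = 1.2)), "\\[0, 1\\]")
})

test_that("simulated choices follow the model's probabilities", {
  spec <- spec_variant("cl1")
  tp <- reference_parameters("cl1")

  # all parameters zero: each alternative drawn with probability 1/3
  tp0 <- tp; tp0$beta[] <- 0; tp0$pi[] <- 0; tp0$delta_o <- 0; tp0$gamma[] <- 0
  d0 <- simulate_choices(generate_design(design_config(seed = 1)),
                         sample_population(population_config(3000, seed = 2)),
                         tp0, "CL", spec, seed = 3)
  share <- mean(d0$tasks$chosen == "optout")
  expect_lt(abs(share - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / nrow(d0$tasks)))

  # scaling utilities towards a dominant alternative pins its share near 1
  tp_big <- tp0
  tp_big$delta_o <- -1000          # opt-out never competitive
  tp_big$beta["effectiveness"] <- 100  # effectiveness differences dominate
  dd <- simulate_choices(generate_design(design_config(seed = 4)),
                         sample_population(population_config(2000, seed = 5)),
                         tp_big, "CL", spec, seed = 6)
  eff_gap <- dd$tasks$a_effectiveness - dd$tasks$b_effectiveness
  decided <- dd$tasks[eff_gap != 0, ]
  best <- ifelse(decided$a_effectiveness > decided$b_effectiveness, "A", "B")
  expect_gt(mean(decided$chosen == best), 0.999)

  # RPL draws one opt-out constant per respondent, shared across tasks
  spec_r <- spec_variant("rpl1")
  tpr <- reference_parameters("rpl1")
  dr <- simulate_choices(generate_design(design_config(seed = 7)),
                         sample_population(population_config(400, seed = 8)),
                         tpr, "RPL", spec_r, seed = 9)
  truth <- attr(dr, "truth")
  expect_length(truth$delta_i, 400L)
  expect_gt(stats::sd(truth$delta_i), 1)

  expect_error(simulate_choices(generate_design(design_config(seed = 1)),
                                sample_population(population_config(10, seed = 1)),
                                reference_parameters("cl2"), "CL", spec,
                                seed = 1),
               "beta block")
})

test_that("the simulator is self-consistent in the Kullback-Leibler sense", {
  spec <- spec_variant("cl1")
  tp <- reference_parameters("cl1")
  d <- small_dataset(800, seed = 47)
  ll_true <- as.numeric(cl_loglik(tp, d, spec))
  set.seed(47)
  worse <- 0L
  for (i in 1:10) {
    p2 <- tp
    p2$beta <- tp$beta * (1 + rnorm(length(tp$beta), 0, 0.5))
    p2$delta_o <- tp$delta_o + rnorm(1, 0, 0.5)
    if (as.numeric(cl_loglik(p2, d, spec)) < ll_true) worse <- worse + 1L
  }
  expect_gte(worse, 9L)
})

test_that("the recovery harness summarises replicates faithfully", {
  dcfg <- design_config(seed = 1)
  pcfg <- population_config(n_respondents = 200, seed = 2)
  tp <- reference_parameters("cl1")
  rec <- recovery_experiment(dcfg, pcfg, tp, "CL", spec_variant("cl1"),
                             n_replicates = 1, seed = 3)
  expect_equal(nrow(rec$summary), 36L)
  # with one replicate the bias is the single-fit deviation and RMSE = |bias|
  expect_equal(rec$summary$rmse, abs(rec$summary$bias), tolerance = 1e-12)
  expect_equal(rec$summary$mean_est - rec$summary$truth, rec$summary$bias)
  expect_true(all(rec$summary$n_ok == 1L))
  expect_length(rec$failures, 0L)
  expect_error(recovery_experiment(dcfg, pcfg, tp, "CL", spec_variant("cl1"),
                                   n_replicates = 0, seed = 1), ">= 1")
})

test_that("estimator bias shrinks as the sample grows", {
  # consistency is asserted on the parameter-averaged absolute deviation:
  # per-parameter deviations at these replicate counts are noise with a
  # fixed scale ratio across sample sizes, so only the aggregate carries a
  # reliable monotone signal
  tp <- reference_parameters("cl1")
  spec <- spec_variant("cl1")
  truth <- c(tp$beta, tp$pi, optout_constant = tp$delta_o, tp$gamma)
  bias <- sapply(c(500L, 2000L, 8000L), function(n) {
    est <- sapply(1:3, function(r) {
      d <- simulate_choices(
        generate_design(design_config(seed = 400 + r)),
        sample_population(population_config(n_respondents = n, seed = 500 + r)),
        tp, "CL", spec, seed = 600 + r)
      fit_conditional_logit(d, spec)$estimate
    })
    abs(rowMeans(est) - truth)
  })
  agg <- colMeans(bias)
  expect_true(all(diff(agg) < 0))
  expect_lt(agg[3], agg[1] / 2)
})

test_that("confidence-interval coverage is near nominal", {
  # 40 replicates at 500 respondents: enough for the parameter-averaged
  # coverage of nominal 95% intervals to discriminate [90%, 99%]
  tp <- reference_parameters("cl1")
  spec <- spec_variant("cl1")
  truth <- c(tp$beta, tp$pi, optout_constant = tp$delta_o, tp$gamma)
  hits <- sapply(1:40, function(r) {
    d <- simulate_choices(
      generate_design(design_config(seed = 700 + r)),
      sample_population(population_config(n_respondents = 500, seed = 800 + r)),
      tp, "CL", spec, seed = 900 + r)
    fit <- fit_conditional_logit(d, spec)
    abs(fit$estimate - truth) <= 1.96 * fit$se
  })
  cover <- mean(hits)
  expect_gte(cover, 0.90)
  expect_lte(cover, 0.99)
})
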