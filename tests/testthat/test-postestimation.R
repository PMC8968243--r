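test_that("willingness to pay is the negative coefficient ratio", {
  f <- manual_fit(reference_parameters("rpl2"), spec_variant("rpl2"))
  p <- reference_parameters("rpl2")

  w <- wtp(f, "protection", "low")
  expect_equal(w$wtp, -p$beta[["protection"]] / p$beta[["cost"]])

  w2 <- wtp(f, "effectiveness", "high", wave2 = TRUE)
  expect_equal(w2$wtp,
               -(p$beta[["effectiveness"]] + p$pi[["effectiveness_x_wave2"]]) /
                 (p$beta[["cost"]] + p$pi[["cost_x_high_income"]]))

  w3 <- wtp(f, "origin_China", "low", republican = TRUE)
  expect_equal(w3$wtp,
               -(p$beta[["origin_China"]] + p$pi[["origin_China_x_republican"]]) /
                 p$beta[["cost"]])

  # zero numerator gives zero WTP regardless of the cost coefficient
  p0 <- p; p0$beta["rec_CDC"] <- 0
  f0 <- manual_fit(p0, spec_variant("rpl2"))
  expect_equal(wtp(f0, "rec_CDC", "low")$wtp, 0)

  # zero denominator is rejected
  pz <- p; pz$beta["cost"] <- 0; pz$pi["cost_x_high_income"] <- 0
  fz <- manual_fit(pz, spec_variant("rpl2"))
  expect_error(wtp(fz, "protection", "low"), "undefined")

  # invariance to rescaling all utility parameters by a common constant
  ps <- p
  ps$beta <- 2.5 * ps$beta; ps$pi <- 2.5 * ps$pi
  ps$delta_o <- 2.5 * ps$delta_o; ps$gamma <- 2.5 * ps$gamma
  fs <- manual_fit(ps, spec_variant("rpl2"))
  expect_equal(wtp(fs, "mild", "high")$wtp, wtp(f, "mild", "high")$wtp,
               tolerance = 1e-12)

  tab <- wtp_table(f)
  expect_true(all(c("effectiveness_wave2", "origin_China_republican") %in%
                    tab$name))
  expect_equal(nrow(tab), 2L * 14L)
})

test_that("delta-method WTP standard errors match a numerical delta method", {
  d <- small_dataset(200, seed = 41)
  fit <- fit_conditional_logit(d, spec_variant("cl1"))
  w <- wtp(fit, "protection", "high")
  # independent route: numerical gradient of the ratio over all parameters
  theta <- fit$estimate
  ratio <- function(th) {
    -(th[["protection"]]) / (th[["cost"]] + th[["cost_x_high_income"]])
  }
  g <- numeric(length(theta))
  for (j in seq_along(theta)) {
    h <- 1e-6 * max(1, abs(theta[j]))
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    g[j] <- (ratio(up) - ratio(dn)) / (2 * h)
  }
  se_num <- sqrt(drop(t(g) %*% fit$covariance %*% g))
  expect_equal(w$se, se_num, tolerance = 1e-4)
  expect_gt(w$se, 0)
})

test_that("odds ratios exponentiate the opt-out coefficients and round-trip", {
  f <- manual_fit(reference_parameters("cl1"), spec_variant("cl1"))
  or <- odds_ratios(f)
  expect_equal(or$odds_ratio, exp(or$coefficient))
  expect_equal(log(or$odds_ratio), or$coefficient, tolerance = 1e-12)
  expect_false("optout_sd" %in% or$name)

  fr <- manual_fit(reference_parameters("rpl1"), spec_variant("rpl1"))
  orr <- odds_ratios(fr)
  expect_true("optout_sd" %in% orr$name)
  expect_true(all(orr$odds_ratio > 0))

  # gamma = 0 gives OR exactly 1
  p0 <- reference_parameters("cl1"); p0$gamma[] <- 0
  expect_true(all(odds_ratios(manual_fit(p0, spec_variant("cl1")))$odds_ratio[-1] == 1))

  # ORs on a real fit inherit significance and carry finite CIs
  d <- small_dataset(150, seed = 43)
  fit <- fit_conditional_logit(d, spec_variant("cl1"))
  or2 <- odds_ratios(fit)
  expect_true(all(or2$ci_low < or2$odds_ratio & or2$odds_ratio < or2$ci_high))
})

test_that("class-assignment odds are direct exponentials of the membership model", {
  tp <- reference_lcl_parameters()
  k <- length(tp$class_params[[1]]$beta_pi) + 1L
  nm <- c(unlist(lapply(1:3, function(q) paste0("class", q, ".x", seq_len(k)))),
          as.vector(t(outer(2:3, colnames(tp$class_gamma),
                            function(q, v) paste0("class", q, ".", v)))))
  theta <- c(rep(0, 3L * k), as.vector(t(tp$class_gamma)))
  lcl <- structure(list(Q = 3L, class_gamma = tp$class_gamma,
                        theta = stats::setNames(theta, nm),
                        se = stats::setNames(rep(0.1, length(theta)), nm),
                        par_names = nm),
                   class = "lcl_fit")
  tab <- class_assignment_odds(lcl)
  i <- which(tab$class == "class3_vs_class1" & tab$name == "male")
  expect_equal(tab$odds_ratio[i], exp(1.0934))
  j <- which(tab$class == "class2_vs_class1" & tab$name == "flu_shot")
  expect_equal(tab$odds_ratio[j], exp(0.8060))
  expect_equal(tab$odds_ratio, exp(tab$coefficient))
  expect_error(class_assignment_odds(structure(list(Q = 1L), class = "lcl_fit")),
               "Q >= 2")
})

test_that("posterior class probabilities follow Bayes' rule", {
  spec <- model_spec("linear_plus_free", n_classes = 2L,
                     class_covariates = "male")
  bn <- c(vaxdce:::attribute_column_names(spec),
          vaxdce:::interaction_column_names(spec))
  mk <- function(costb, delta) {
    v <- stats::setNames(rep(0, length(bn)), bn)
    v["cost"] <- costb
    list(beta_pi = v, delta_o = delta)
  }
  cg <- matrix(c(0.4, -0.8), 1, 2, dimnames = list("class2", c("constant", "male")))
  lcl <- structure(list(Q = 2L, spec = spec,
                        class_params = list(mk(-0.01, 0.5), mk(-0.001, -1)),
                        class_gamma = cg, class_covariates = "male"),
                   class = "lcl_fit")
  resp <- respondent(1, male = 1)
  tasks <- data.frame(resp_id = 1, task_index = 1:2,
                      chosen = c("A", "optout"),
                      a_cost = c(0, 100), a_effectiveness = 60,
                      a_incubation = 7, a_protection = 12, a_mild = 1,
                      a_severe = 1, a_recommender = "PCP",
                      a_origin = "Germany", a_introduced = 6,
                      b_cost = c(175, 50), b_effectiveness = 60,
                      b_incubation = 7, b_protection = 12, b_mild = 1,
                      b_severe = 1, b_recommender = "PCP",
                      b_origin = "Germany", b_introduced = 6)
  d <- dce_data(tasks, resp)
  h <- posterior_class_probabilities(lcl, d)

  # by-hand Bayes: class likelihoods from per-task softmax, prior from the
  # membership logit
  lik_class <- function(cp) {
    out <- 1
    for (t in 1:2) {
      uA <- cp$beta_pi[["free"]] * (tasks$a_cost[t] == 0) +
        cp$beta_pi[["cost"]] * tasks$a_cost[t]
      uB <- cp$beta_pi[["free"]] * (tasks$b_cost[t] == 0) +
        cp$beta_pi[["cost"]] * tasks$b_cost[t]
      uO <- cp$delta_o
      pr <- exp(c(uA, uB, uO)) / sum(exp(c(uA, uB, uO)))
      out <- out * pr[match(tasks$chosen[t], c("A", "B", "optout"))]
    }
    out
  }
  L <- c(lik_class(lcl$class_params[[1]]), lik_class(lcl$class_params[[2]]))
  eta <- c(0, cg["class2", "constant"] + cg["class2", "male"])
  prior <- exp(eta) / sum(exp(eta))
  expect_equal(unname(h[1, ]), prior * L / sum(prior * L), tolerance = 1e-12)
  expect_lt(abs(sum(h[1, ]) - 1), 1e-12)

  # identical class likelihoods and flat prior give 1/Q
  lcl_flat <- lcl
  lcl_flat$class_params[[2]] <- lcl_flat$class_params[[1]]
  lcl_flat$class_gamma[] <- 0
  hf <- posterior_class_probabilities(lcl_flat, d)
  expect_equal(unname(hf[1, ]), c(0.5, 0.5), tolerance = 1e-12)

  # a class assigning ~0 likelihood loses its posterior mass (log-space safe)
  lcl_ext <- lcl
  lcl_ext$class_params[[2]]$delta_o <- -400
  lcl_ext$class_params[[2]]$beta_pi["cost"] <- -3  # hates the chosen options
  he <- posterior_class_probabilities(lcl_ext, d)
  expect_gt(he[1, 1], 0.999)
  expect_true(all(is.finite(he)))
})

test_that("random class assignment is seeded and consistent with posteriors", {
  tp <- reference_lcl_parameters()
  lcl <- structure(list(Q = 3L, spec = tp$spec, class_params = tp$class_params,
                        class_gamma = tp$class_gamma,
                        class_covariates = tp$class_covariates),
                   class = "lcl_fit")
  d <- simulate_choices(generate_design(design_config(seed = 71)),
                        sample_population(population_config(n_respondents = 1500,
                                                            seed = 72)),
                        tp, "LCL", tp$spec, seed = 73)
  a1 <- assign_classes(lcl, d, seed = 9)
  a2 <- assign_classes(lcl, d, seed = 9)
  expect_identical(a1$labels, a2$labels)
  # realized shares within binomial error of the expected (mean posterior)
  tol <- 3 * sqrt(pmax(a1$expected_shares * (1 - a1$expected_shares), 1e-4) / 1500)
  expect_true(all(abs(a1$realized_shares - a1$expected_shares) < tol))

  # degenerate posteriors make assignment deterministic
  lcl_det <- lcl
  lcl_det$class_gamma <- matrix(c(-200, -200, 0, 0), 2, 2,
                                dimnames = list(c("class2", "class3"),
                                                c("constant", "male")))
  lcl_det$class_covariates <- "male"
  lcl_det$class_params <- lapply(lcl_det$class_params, function(cp) {
    cp$beta_pi[] <- 0; cp$delta_o <- 0; cp
  })
  b1 <- assign_classes(lcl_det, d, seed = 1)
  b2 <- assign_classes(lcl_det, d, seed = 2)
  expect_identical(b1$labels, b2$labels)
  expect_true(all(b1$labels == 1L))
})

test_that("scenario curves are coherent probability sweeps", {
  f <- manual_fit(reference_parameters("rpl2"), spec_variant("rpl2"))
  b <- vaccine_profile(0, 95, 21, 12, 4, 10, "PCP", "Germany", 6)
  g <- seq(0, 700, length.out = 100)
  sc <- scenario_curves(f, b, b, representative_respondent(), "cost", g,
                        integration = list(method = "quadrature", order = 30))
  expect_true(all(abs(rowSums(sc$curve[, -1]) - 1) < 1e-10))
  # identical profiles at the shared grid point give equal probabilities
  expect_equal(sc$curve$P_A[1], sc$curve$P_B[1], tolerance = 1e-12)
  # P(A) falls strictly in cost, P(B) rises
  expect_true(all(diff(sc$curve$P_A) < 0))
  expect_true(all(diff(sc$curve$P_B) > 0))

  # fixed-constant fit needs no integration and behaves identically
  fc <- manual_fit(reference_parameters("cl1"), spec_variant("cl1"))
  sc2 <- scenario_curves(fc, b, b, representative_respondent(), "cost", g)
  expect_true(all(diff(sc2$curve$P_A) < 0))

  expect_error(scenario_curves(f, b, b, representative_respondent(), "cost",
                               c(-10, 0, 10)), "cost")
  expect_error(scenario_curves(f, b, b, representative_respondent(),
                               "flavour", g), "unknown attribute")
})
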