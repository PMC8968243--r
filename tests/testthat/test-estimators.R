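spec1 <- spec_variant("cl1")

test_that("conditional-logit likelihood equals -N log 3 at zero parameters", {
  d <- small_dataset(30, seed = 11)
  p0 <- reference_parameters("cl1")
  p0$beta[] <- 0; p0$pi[] <- 0; p0$delta_o <- 0; p0$gamma[] <- 0
  expect_equal(as.numeric(cl_loglik(p0, d, spec1)),
               -nrow(d$tasks) * log(3), tolerance = 1e-12)
  expect_error(cl_loglik(p0, dce_data(d$tasks[0, ], d$respondents), spec1),
               "empty")
})

test_that("analytic gradients match central finite differences", {
  d <- small_dataset(25, seed = 13)
  set.seed(13)
  pars <- random_parameters(spec1)
  pack <- function(p) c(p$beta, p$pi, p$delta_o, p$gamma)
  unpack_eval <- function(v) {
    K <- length(pars$beta); ni <- length(pars$pi)
    p <- pars
    p$beta[] <- v[seq_len(K)]
    p$pi[] <- v[K + seq_len(ni)]
    p$delta_o <- v[K + ni + 1]
    p$gamma[] <- v[(K + ni + 2):length(v)]
    p
  }
  theta <- pack(pars)
  g <- attr(cl_loglik(pars, d, spec1), "gradient")
  for (j in sample(seq_along(theta), 8)) {
    h <- 1e-6 * max(1, abs(theta[j]))
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    fd <- (as.numeric(cl_loglik(unpack_eval(up), d, spec1)) -
             as.numeric(cl_loglik(unpack_eval(dn), d, spec1))) / (2 * h)
    expect_equal(unname(g[j]), fd, tolerance = 1e-6)
  }

  # simulated-likelihood gradient against finite differences
  spec_r <- spec_variant("rpl1")
  dr <- small_dataset(20, model = "rpl1", seed = 17)
  draws <- draw_set(20, R = 50)
  set.seed(17)
  pr <- random_parameters(spec_r)
  pr$sigma_o <- 1.5
  gr <- attr(rpl_simulated_loglik(pr, dr, spec_r, draws), "gradient")
  K <- length(pr$beta); ni <- length(pr$pi)
  idx_sigma <- K + ni + 2L
  for (j in c(1L, K + ni + 1L, idx_sigma, idx_sigma + 3L)) {
    evalp <- function(v) {
      p <- pr
      p$beta[] <- v[seq_len(K)]; p$pi[] <- v[K + seq_len(ni)]
      p$delta_o <- v[K + ni + 1]; p$sigma_o <- v[idx_sigma]
      p$gamma[] <- v[(idx_sigma + 1):length(v)]
      as.numeric(rpl_simulated_loglik(p, dr, spec_r, draws))
    }
    theta <- c(pr$beta, pr$pi, pr$delta_o, pr$sigma_o, pr$gamma)
    h <- 1e-6 * max(1, abs(theta[j]))
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    expect_equal(unname(gr[j]), (evalp(up) - evalp(dn)) / (2 * h), tolerance = 1e-5)
  }
})

test_that("the maximizer agrees with a dense grid search on one coefficient", {
  d <- small_dataset(10, seed = 19)
  p <- reference_parameters("cl1")
  p$beta[] <- 0; p$pi[] <- 0; p$delta_o <- 0; p$gamma[] <- 0
  profile_ll <- function(b) {
    p$beta["effectiveness"] <- b
    as.numeric(cl_loglik(p, d, spec1))
  }
  grid <- seq(-2, 2, by = 0.001)
  b_grid <- grid[which.max(vapply(grid, profile_ll, 0))]
  opt <- vaxdce:::maximize_bfgs(0, function(b) {
    p$beta["effectiveness"] <- b
    ll <- cl_loglik(p, d, spec1)
    list(loglik = as.numeric(ll),
         gradient = attr(ll, "gradient")[["effectiveness"]])
  })
  expect_lt(abs(opt$theta - b_grid), 0.001)
})

test_that("conditional logit recovers its generating parameters", {
  tp <- reference_parameters("cl1")
  d <- small_dataset(500, seed = 23)
  fit <- fit_conditional_logit(d, spec1)
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-5)
  truth <- c(tp$beta, tp$pi, optout_constant = tp$delta_o, tp$gamma)
  z <- (fit$estimate - truth) / fit$se
  expect_true(all(abs(z) < 3.5))
  expect_true(all(diag(fit$covariance) > 0))
  # BIC arithmetic identity
  expect_equal(fit$bic, -2 * fit$loglik + fit$k * log(fit$n_choices))
  # refit on the identical dataset gives a bit-identical log-likelihood
  fit2 <- fit_conditional_logit(d, spec1)
  expect_identical(fit$loglik, fit2$loglik)
})

test_that("likelihood is invariant to dataset row order", {
  d <- small_dataset(60, seed = 29)
  p <- reference_parameters("cl1")
  set.seed(29)
  perm <- sample(nrow(d$tasks))
  d_perm <- dce_data(d$tasks[perm, ], d$respondents)
  expect_equal(as.numeric(cl_loglik(p, d, spec1)),
               as.numeric(cl_loglik(p, d_perm, spec1)), tolerance = 1e-10)
  rperm <- sample(nrow(d$respondents))
  d_perm2 <- dce_data(d$tasks, d$respondents[rperm, ])
  expect_equal(as.numeric(cl_loglik(p, d, spec1)),
               as.numeric(cl_loglik(p, d_perm2, spec1)), tolerance = 1e-10)
})

test_that("degenerate opt-out data trigger a separation warning", {
  spec0 <- model_spec("linear", optout_covariates = character(0))
  tp <- reference_parameters("cl1")
  tp$gamma <- numeric(0)
  tp$delta_o <- -30  # opt-out never chosen
  d <- simulate_choices(generate_design(design_config(seed = 61)),
                        sample_population(population_config(n_respondents = 120,
                                                            seed = 62)),
                        tp, "CL", spec0, seed = 63)
  expect_equal(sum(d$tasks$chosen == "optout"), 0L)
  expect_warning(fit_conditional_logit(d, spec0),
                 "separation.*optout_constant")
})

test_that("simulated likelihood collapses to the conditional logit at sigma = 0", {
  spec_r <- spec_variant("rpl1")
  d <- small_dataset(40, model = "rpl1", seed = 31)
  p <- reference_parameters("rpl1")
  p$sigma_o <- 0
  for (R in c(1L, 7L, 40L)) {
    sl <- rpl_simulated_loglik(p, d, spec_r, draw_set(40, R = R))
    expect_equal(as.numeric(sl), as.numeric(cl_loglik(p, d, spec_r)),
                 tolerance = 1e-10)
  }
  expect_error(draw_set(40, R = 0), "R must be")
})

test_that("simulated likelihood is stable in the number of draws", {
  spec_r <- spec_variant("rpl2")
  d <- small_dataset(20, model = "rpl2", seed = 7)
  p <- reference_parameters("rpl2")
  ll1 <- as.numeric(rpl_simulated_loglik(p, d, spec_r, draw_set(20, R = 1000)))
  ll2 <- as.numeric(rpl_simulated_loglik(p, d, spec_r, draw_set(20, R = 2000)))
  # integration error at these draw counts is far below the likelihood scale
  expect_lt(abs(ll1 - ll2), 0.02)
})

test_that("the panel mixed logit recovers a positive opt-out dispersion", {
  spec_r <- spec_variant("rpl2")
  tp <- reference_parameters("rpl2")
  d <- small_dataset(200, model = "rpl2", seed = 5)
  fit <- fit_rpl(d, spec_r, options = list(R = 100, seed = 1))
  expect_true(fit$converged)
  i <- match("optout_sd", fit$par_names)
  z <- (fit$estimate[i] - tp$sigma_o) / fit$se[i]
  expect_lt(abs(z), 3)
  expect_gt(fit$estimate[i], 0)
  expect_equal(fit$bic, -2 * fit$loglik + fit$k * log(fit$n_choices))
})

test_that("fitting the mixed logit on fixed-constant data finds sigma near 0", {
  d <- small_dataset(300, model = "cl1", seed = 53)
  fit_r <- fit_rpl(d, spec_variant("rpl1"), options = list(R = 100, seed = 1))
  fit_c <- fit_conditional_logit(d, spec1)
  i <- match("optout_sd", fit_r$par_names)
  expect_lt(fit_r$estimate[i] / fit_r$se[i], qnorm(0.995))
  expect_lt(abs(fit_r$loglik - fit_c$loglik), 2)
  expect_gte(fit_r$loglik, fit_c$loglik - 1e-6)
})

test_that("model selection ranks by BIC and validates its inputs", {
  mk <- function(loglik, k, n) {
    structure(list(model_kind = "CL", loglik = loglik, k = k,
                   bic = -2 * loglik + k * log(n), n_choices = n),
              class = "dce_fit")
  }
  a <- mk(-1000, 10, 700)
  b <- mk(-1000, 12, 700)
  tab <- model_selection(list(small = a, large = b))
  expect_equal(tab$model[1], "small")
  expect_true(tab$selected[1] && !tab$selected[2])

  single <- model_selection(list(only = a))
  expect_true(single$selected)

  expect_error(model_selection(list(a, mk(-900, 10, 900))),
               "different numbers of choices")
})
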