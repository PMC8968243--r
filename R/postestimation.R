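# Post-estimation transforms: willingness to pay, odds ratios, posterior
# class assignment and scenario probability curves.

theta_index <- function(fit, name) {
  i <- match(name, fit$par_names)
  if (is.na(i)) stop("parameter not in fit: ", name)
  i
}

#' Marginal willingness to pay for a vaccine attribute
#'
#' Computes \eqn{\omega_k = -\beta_k / \beta_{cost}} — the marginal rate of
#' substitution between attribute \eqn{k} and out-of-pocket cost — from a
#' fitted model. For the high-income group the cost coefficient is
#' \eqn{\beta_{cost} + \pi_{cost \times high}}; with \code{wave2 = TRUE} the
#' effectiveness numerator adds the wave-2 interaction, and with
#' \code{republican = TRUE} the China-origin numerator adds the
#' China x Republican interaction. Standard errors come from the delta method
#' on the ratio; confidence intervals are normal 95\%.
#'
#' @param fit a \code{dce_fit}.
#' @param attribute an encoded attribute column name (e.g.
#'   \code{"effectiveness"}, \code{"origin_China"}, \code{"rec_Media"}).
#' @param income_group \code{"low"} or \code{"high"}.
#' @param wave2 logical; add the effectiveness x wave-2 shift.
#' @param republican logical; add the China x Republican shift.
#' @return One-row data.frame: name, group, wtp (US$ per attribute unit), se,
#'   ci_low, ci_high, significant (of the numerator at 5\%).
#' @export
wtp <- function(fit, attribute, income_group = c("low", "high"),
                wave2 = FALSE, republican = FALSE) {
  income_group <- match.arg(income_group)
  est <- fit$estimate
  num_idx <- theta_index(fit, attribute)
  num_w <- stats::setNames(1, fit$par_names[num_idx])
  label <- attribute
  if (wave2 && attribute == "effectiveness") {
    num_w <- c(num_w, effectiveness_x_wave2 = 1)
    label <- "effectiveness_wave2"
  }
  if (republican && attribute == "origin_China") {
    num_w <- c(num_w, origin_China_x_republican = 1)
    label <- "origin_China_republican"
  }
  den_w <- c(cost = 1)
  if (income_group == "high") den_w <- c(den_w, cost_x_high_income = 1)
  missing_par <- setdiff(c(names(num_w), names(den_w)), fit$par_names)
  if (length(missing_par)) {
    stop("fit does not contain parameter(s): ",
         paste(missing_par, collapse = ", "))
  }
  a <- sum(est[names(num_w)] * num_w)
  c_ <- sum(est[names(den_w)] * den_w)
  if (abs(c_) < 1e-10) stop("WTP undefined: group cost coefficient is zero")
  w <- -a / c_
  # delta method: grad wrt (numerator coords, denominator coords)
  idx <- match(c(names(num_w), names(den_w)), fit$par_names)
  g <- c(-num_w / c_, den_w * a / c_^2)
  V <- fit$covariance[idx, idx, drop = FALSE]
  se <- sqrt(drop(t(g) %*% V %*% g))
  num_se <- sqrt(drop(t(num_w) %*%
                        fit$covariance[match(names(num_w), fit$par_names),
                                       match(names(num_w), fit$par_names),
                                       drop = FALSE] %*% num_w))
  data.frame(name = label, group = income_group, wtp = w, se = se,
             ci_low = w - 1.96 * se, ci_high = w + 1.96 * se,
             significant = abs(a / num_se) > stats::qnorm(0.975),
             stringsAsFactors = FALSE)
}

#' Full willingness-to-pay table for both income groups
#'
#' One row per non-cost attribute column (plus the wave-2 effectiveness and
#' Republican China rows) for each income group. Values are always computed;
#' non-significant numerators are flagged rather than suppressed.
#'
#' @param fit a \code{dce_fit}.
#' @return data.frame of \code{\link{wtp}} rows.
#' @export
wtp_table <- function(fit) {
  attrs <- setdiff(attribute_column_names(fit$spec), c("free", "cost"))
  rows <- list()
  for (grp in c("low", "high")) {
    for (a in attrs) {
      rows[[length(rows) + 1L]] <- wtp(fit, a, grp)
      if (a == "effectiveness") {
        rows[[length(rows) + 1L]] <- wtp(fit, a, grp, wave2 = TRUE)
      }
      if (a == "origin_China") {
        rows[[length(rows) + 1L]] <- wtp(fit, a, grp, republican = TRUE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Odds ratios of opting out
#'
#' Exponentiates the opt-out index coefficients (and the opt-out constant
#' mean; for random-constant models also its standard deviation). An odds
#' ratio above 1 means the covariate raises the odds of choosing no vaccine.
#' Significance is inherited from the underlying coefficients and must be
#' read against 1.
#'
#' @param fit a \code{dce_fit}.
#' @return data.frame: name, coefficient, odds_ratio, ci_low, ci_high, p,
#'   stars.
#' @export
odds_ratios <- function(fit) {
  nm <- c("optout_constant",
          if (fit$model_kind == "RPL") "optout_sd",
          fit$spec$optout_covariates)
  idx <- match(nm, fit$par_names)
  est <- unname(fit$estimate[idx])
  se <- unname(fit$se[idx])
  if (is.null(fit$covariance)) {
    warning("no covariance available; confidence intervals omitted")
    se <- rep(NA_real_, length(est))
  }
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(name = nm, coefficient = est, odds_ratio = exp(est),
             ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
             p = p, stars = as.character(significance_stars(p)),
             stringsAsFactors = FALSE)
}

#' Odds ratios of latent-class assignment
#'
#' Exponentiates the multinomial-logit class-membership coefficients of each
#' non-reference class, giving the multiplicative change in the odds of
#' belonging to that class (relative to class 1) per unit covariate change.
#'
#' @param lcl an \code{lcl_fit} with \code{Q >= 2}.
#' @return data.frame: class, name, coefficient, odds_ratio, ci_low, ci_high,
#'   p, stars.
#' @export
class_assignment_odds <- function(lcl) {
  if (lcl$Q < 2L) stop("class assignment odds require Q >= 2")
  rows <- list()
  for (q in seq(2L, lcl$Q)) {
    for (v in colnames(lcl$class_gamma)) {
      pname <- paste0("class", q, ".", v)
      i <- match(pname, lcl$par_names)
      est <- unname(lcl$theta[i]); se <- unname(lcl$se[i])
      z <- est / se; p <- 2 * stats::pnorm(-abs(z))
      rows[[length(rows) + 1L]] <- data.frame(
        class = paste0("class", q, "_vs_class1"), name = v,
        coefficient = est, odds_ratio = exp(est),
        ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
        p = p, stars = as.character(significance_stars(p)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Posterior class-membership probabilities
#'
#' Bayes update of the multinomial-logit prior with each respondent's
#' class-conditional likelihood of the observed choice sequence:
#' \eqn{h_{iq} = \pi_{iq} L_{iq} / \sum_q \pi_{iq} L_{iq}}, computed in log
#' space so no class likelihood underflows to a zero division.
#'
#' @param lcl an \code{lcl_fit}.
#' @param data a \code{\link{dce_data}} with the respondents' full task
#'   sequences (defaults to recomputing on the data layout used at fit time is
#'   not stored; pass the dataset explicitly).
#' @return Matrix (respondents x Q) of posterior probabilities, rows summing
#'   to 1, with resp_id rownames.
#' @export
posterior_class_probabilities <- function(lcl, data) {
  mm <- build_model_matrices(data, lcl$spec, optout_covariates = character(0))
  K <- length(mm$beta_names) + 1L
  LL <- vapply(lcl$class_params, function(cp) {
    class_resp_loglik(c(cp$beta_pi, cp$delta_o), mm)
  }, numeric(mm$n_resp))
  lp <- if (lcl$Q > 1L) {
    WR1 <- cbind(1, vapply(stats::setNames(lcl$class_covariates,
                                           lcl$class_covariates),
                           function(nm) covariate_scaled(data$respondents, nm),
                           numeric(nrow(data$respondents))))
    membership_logprob(lcl$class_gamma, WR1)
  } else matrix(0, mm$n_resp, 1L)
  lj <- lp + LL
  h <- exp(lj - row_logsumexp(lj))
  rownames(h) <- as.character(mm$resp_ids)
  colnames(h) <- paste0("class", seq_len(lcl$Q))
  h
}

#' Randomly assign respondents to latent classes from their posteriors
#'
#' Draws one class label per respondent from its posterior distribution
#' (seeded), and reports realized shares alongside the expected shares (mean
#' posterior per class).
#'
#' @param lcl an \code{lcl_fit}.
#' @param data the \code{\link{dce_data}} the posteriors are conditioned on.
#' @param seed integer seed for the categorical draws.
#' @return list with \code{labels} (named integer vector), \code{realized_shares},
#'   \code{expected_shares}, \code{posterior}.
#' @export
assign_classes <- function(lcl, data, seed = 1L) {
  h <- posterior_class_probabilities(lcl, data)
  labels <- withr_seed(seed, apply(h, 1L, function(p) {
    sample.int(length(p), 1L, prob = p)
  }))
  realized <- tabulate(labels, nbins = lcl$Q) / length(labels)
  list(labels = labels,
       realized_shares = stats::setNames(realized, colnames(h)),
       expected_shares = stats::setNames(colMeans(h), colnames(h)),
       posterior = h)
}

#' Scenario probability curves
#'
#' Sweeps one attribute of vaccine A over a grid while holding vaccine B and
#' the respondent fixed, and reports the probability triple P(A), P(B),
#' P(opt out) at each grid point. For random-constant (RPL) fits the triple is
#' the population average over the opt-out constant distribution, integrated
#' by seeded Monte Carlo draws or by Gauss-Hermite quadrature. Crossing
#' points of P(A) with P(opt out) are located by linear interpolation.
#'
#' @param fit a \code{dce_fit}.
#' @param profile_A,profile_B \code{\link{vaccine_profile}}s.
#' @param resp one-row respondent record (see
#'   \code{\link{representative_respondent}}).
#' @param varied_attribute one of the nine attribute fields of a profile.
#' @param grid numeric (or character for enum attributes) grid of values;
#'   every value must lie in the attribute's domain.
#' @param integration list: \code{method} ("mc", "quadrature", or
#'   "conditional" to evaluate at the mean opt-out constant without
#'   integrating), \code{R} (draws, default 10000), \code{scheme} ("halton"
#'   normal draws, the default, or "pseudo_random" with \code{seed}),
#'   \code{order} (quadrature nodes, default 30).
#' @return Object of class \code{scenario_curve}: list with \code{curve}
#'   (data.frame grid, P_A, P_B, P_optout), \code{crossings} (P(A)=P(optout)
#'   grid locations), the descriptor of the respondent and integration
#'   metadata.
#' @export
scenario_curves <- function(fit, profile_A, profile_B, resp, varied_attribute,
                            grid, integration = list()) {
  if (!varied_attribute %in% ATTRIBUTE_FIELDS) {
    stop("unknown attribute: ", varied_attribute)
  }
  method <- integration$method %||% "mc"
  params <- list(beta = fit$estimate[attribute_column_names(fit$spec)],
                 pi = fit$estimate[interaction_column_names(fit$spec)],
                 delta_o = unname(fit$estimate["optout_constant"]),
                 sigma_o = if ("optout_sd" %in% fit$par_names) {
                   unname(fit$estimate["optout_sd"])
                 } else 0,
                 gamma = fit$estimate[fit$spec$optout_covariates])
  spec <- fit$spec
  bp <- c(params$beta, params$pi)
  w <- encode_optout(resp, spec)
  uO_base <- params$delta_o + sum(w * params$gamma)
  if (params$sigma_o > 0 && method != "conditional") {
    if (method == "mc") {
      R <- integration$R %||% 10000L
      z <- if ((integration$scheme %||% "halton") == "halton") {
        stats::qnorm(halton_sequence(R))
      } else {
        withr_seed(integration$seed %||% 1L, stats::rnorm(R))
      }
      nodes <- params$delta_o + params$sigma_o * z
      weights <- rep(1 / R, R)
    } else {
      gh <- gauss_hermite_normal(integration$order %||% 30L,
                                 mean = params$delta_o, sd = params$sigma_o)
      nodes <- gh$nodes
      weights <- gh$weights
    }
    uO_shift <- nodes - params$delta_o
  } else {
    uO_shift <- 0
    weights <- 1
  }
  uB <- sum(encode_vaccine(profile_B, resp, spec) * bp)
  eval_point <- function(val) {
    pa <- profile_A
    pa[[varied_attribute]] <- val
    validate_profile(pa)
    uA <- sum(encode_vaccine(pa, resp, spec) * bp)
    uO <- uO_base + uO_shift
    m <- pmax(uA, uB, uO)
    eA <- exp(uA - m); eB <- exp(uB - m); eO <- exp(uO - m)
    den <- eA + eB + eO
    c(P_A = sum(weights * eA / den), P_B = sum(weights * eB / den),
      P_optout = sum(weights * eO / den))
  }
  probs <- t(vapply(grid, eval_point, c(P_A = 0, P_B = 0, P_optout = 0)))
  curve <- data.frame(grid = grid, probs)
  crossings <- numeric(0)
  if (is.numeric(grid) && length(grid) > 1L) {
    d <- curve$P_A - curve$P_optout
    sgn <- which(d[-1] * d[-length(d)] < 0)
    for (i in sgn) {
      t0 <- d[i] / (d[i] - d[i + 1L])
      crossings <- c(crossings, grid[i] + t0 * (grid[i + 1L] - grid[i]))
    }
  }
  structure(list(curve = curve, crossings = crossings,
                 varied_attribute = varied_attribute,
                 respondent = resp,
                 integration = list(method = method,
                                    R = if (method == "mc") length(uO_shift) else NA,
                                    order = if (method == "quadrature") length(uO_shift) else NA,
                                    seed = integration$seed %||% 1L)),
            class = "scenario_curve")
}

#' @export
print.scenario_curve <- function(x, ...) {
  cat("Scenario curve over", x$varied_attribute, "(",
      nrow(x$curve), "grid points,", x$integration$method, "integration )\n")
  if (length(x$crossings)) {
    cat("  P(A) = P(optout) at", x$varied_attribute, "=",
        paste(format(x$crossings, digits = 4), collapse = ", "), "\n")
  }
  print(utils::head(x$curve))
  invisible(x)
}

#' Representative respondent for scenario analysis
#'
#' A white male aged 42 with BMI 31 and household income $62,236 (sample
#' means of the emulated study population); all other covariates default to 0
#' and can be overridden.
#'
#' @param ... covariate overrides passed to \code{\link{respondent}}.
#' @return One-row respondent record.
#' @export
representative_respondent <- function(...) {
  defaults <- list(id = 0L, male = 1, age = 42, bmi = 31,
                   household_income = 62236)
  args <- utils::modifyList(defaults, list(...))
  do.call(respondent, args)
}

#' Write a WTP or OR table as delimited text
#'
#' @param table data.frame from \code{\link{wtp_table}},
#'   \code{\link{odds_ratios}} or \code{\link{class_assignment_odds}}.
#' @param path output CSV path.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
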