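# Quasi-Newton maximisation with analytic gradients, plus covariance from the
# numerically differentiated gradient (central differences).

# BFGS to the neighbourhood of the optimum, then Newton polish with the
# central-difference Hessian of the analytic gradient until the gradient norm
# drops below `tol`. The Hessian of the final iterate is returned so the
# covariance can reuse it.
maximize_bfgs <- function(theta0, fn_gr, tol = 1e-6, maxit = 500L) {
  negf <- function(th) -fn_gr(th)$loglik
  negg <- function(th) -fn_gr(th)$gradient
  opt <- stats::optim(theta0, negf, negg, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  theta <- opt$par
  iterations <- opt$counts[["function"]]
  cur <- fn_gr(theta)
  H <- gradient_hessian(theta, fn_gr)
  stale <- 0L
  for (polish in seq_len(25L)) {
    gnorm <- sqrt(sum(cur$gradient^2))
    if (gnorm < tol) break
    dir <- tryCatch(-solve(H, cur$gradient), error = function(e) NULL)
    if (is.null(dir) || !all(is.finite(dir))) dir <- cur$gradient
    step <- 1
    improved <- FALSE
    for (ls in 1:12) {
      cand <- theta + step * dir
      new <- fn_gr(cand)
      if (is.finite(new$loglik) && new$loglik >= cur$loglik) {
        theta <- cand
        cur <- new
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    iterations <- iterations + 1L
    stale <- stale + 1L
    if (!improved || stale >= 5L) {
      H <- gradient_hessian(theta, fn_gr)
      stale <- 0L
      if (!improved) next
    }
  }
  if (stale > 0L) H <- gradient_hessian(theta, fn_gr)
  gnorm <- sqrt(sum(cur$gradient^2))
  list(theta = theta, loglik = cur$loglik, grad_norm = gnorm,
       converged = gnorm < tol * max(1, sqrt(length(theta))),
       iterations = iterations, hessian = H)
}

# Hessian of the log-likelihood by central differences of the analytic
# gradient; returns the covariance solve(-H) (pseudo-inverse fallback).
gradient_hessian <- function(theta, fn_gr, h = 1e-5) {
  k <- length(theta)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    step <- h * max(1, abs(theta[j]))
    tp <- tm <- theta
    tp[j] <- tp[j] + step
    tm[j] <- tm[j] - step
    H[, j] <- (fn_gr(tp)$gradient - fn_gr(tm)$gradient) / (2 * step)
  }
  (H + t(H)) / 2
}

covariance_from_hessian <- function(H, par_names) {
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V)) || any(diag(V) <= 0)) {
    eg <- eigen(-H, symmetric = TRUE)
    pos <- pmax(eg$values, 1e-10)
    V <- eg$vectors %*% diag(1 / pos, length(pos)) %*% t(eg$vectors)
    warning("Hessian not positive definite at the optimum; ",
            "covariance from regularized pseudo-inverse")
  }
  dimnames(V) <- list(par_names, par_names)
  V
}

warn_separation <- function(theta, par_names, bound = 10) {
  hit <- abs(theta) > bound
  # income is in $10K units and utilities are on a unit logit scale, so any
  # coefficient drifting past `bound` signals (quasi-)separation
  if (any(hit)) {
    warning("possible separation: coefficient(s) diverging for ",
            paste(par_names[hit], collapse = ", "))
  }
}

new_dce_fit <- function(model_kind, spec, mm, opt, V, n_resp, n_choices,
                        draws_used = 0L, seed = NA_integer_, random) {
  k <- length(opt$theta)
  par_names <- theta_names(mm, random)
  params <- unpack_theta(opt$theta, mm, random)
  est <- stats::setNames(opt$theta, par_names)
  if (random) {
    i_sd <- length(mm$beta_names) + 2L
    est[i_sd] <- abs(est[i_sd])
  }
  structure(list(
    model_kind = model_kind, spec = spec, params = params,
    estimate = est, par_names = par_names,
    loglik = opt$loglik,
    bic = -2 * opt$loglik + k * log(n_choices),
    covariance = V, se = sqrt(pmax(diag(V), 0)),
    k = k, n_respondents = n_resp, n_choices = n_choices,
    draws_used = draws_used, seed = seed,
    converged = opt$converged, iterations = opt$iterations,
    grad_norm = opt$grad_norm
  ), class = "dce_fit")
}

#' Fit the conditional logit model
#'
#' Maximises the conditional-logit likelihood by quasi-Newton (BFGS) with
#' exact analytic gradients, starting from the zero vector. The covariance is
#' the inverse of the numerical Hessian at the optimum; convergence requires
#' gradient norm below \code{tol}.
#'
#' @param data a \code{\link{dce_data}}.
#' @param spec a \code{\link{model_spec}} with \code{optout_random = FALSE}.
#' @param options list; \code{tol} (gradient-norm tolerance, default 1e-6),
#'   \code{maxit} (default 500).
#' @return An \code{\link[=print.dce_fit]{dce_fit}} with estimates, SEs,
#'   log-likelihood and BIC (\eqn{-2\ell + k \ln n} with \eqn{n} the number of
#'   choice tasks).
#' @export
fit_conditional_logit <- function(data, spec, options = list()) {
  if (spec$optout_random) stop("spec$optout_random must be FALSE for the conditional logit")
  mm <- build_model_matrices(data, spec)
  fn_gr <- function(th) cl_core(th, mm)
  theta0 <- rep(0, length(mm$beta_names) + 1L + length(mm$w_names))
  opt <- maximize_bfgs(theta0, fn_gr,
                       tol = options$tol %||% 1e-6,
                       maxit = options$maxit %||% 500L)
  if (!opt$converged) {
    warning("conditional logit did not reach gradient tolerance (|g| = ",
            format(opt$grad_norm, digits = 3), ")")
  }
  par_names <- theta_names(mm, random = FALSE)
  warn_separation(opt$theta, par_names)
  V <- covariance_from_hessian(opt$hessian, par_names)
  new_dce_fit("CL", spec, mm, opt, V, mm$n_resp, nrow(data$tasks),
              random = FALSE)
}

#' Fit the panel random-parameter logit by maximum simulated likelihood
#'
#' The opt-out constant is normally distributed across respondents and shared
#' across each respondent's tasks. Estimation maximises the simulated
#' likelihood over (beta, pi, gamma, delta_o, sigma_o); sigma_o is optimised
#' unconstrained through its absolute value and reported nonnegative. Start
#' values are the conditional-logit estimates with sigma_o = 0.1.
#'
#' @param data a \code{\link{dce_data}}.
#' @param spec a \code{\link{model_spec}} with \code{optout_random = TRUE}.
#' @param draws a \code{\link{draw_set}}; default Halton, \code{R = 500}.
#' @param options list; \code{tol}, \code{maxit}, \code{R} (draws when
#'   \code{draws} is NULL), \code{seed} (draw seed).
#' @return A \code{dce_fit} with \code{model_kind = "RPL"}.
#' @export
fit_rpl <- function(data, spec, draws = NULL, options = list()) {
  if (!spec$optout_random) stop("spec$optout_random must be TRUE for the random-parameter logit")
  mm <- build_model_matrices(data, spec)
  seed <- options$seed %||% 1L
  if (is.null(draws)) {
    draws <- draw_set(mm$n_resp, R = options$R %||% 500L,
                      scheme = options$scheme %||% "halton", seed = seed)
  }
  if (nrow(draws$values) < mm$n_resp) stop("draw set has fewer blocks than respondents")
  Z <- draws$values[seq_len(mm$n_resp), , drop = FALSE]
  cl_spec <- spec
  cl_spec$optout_random <- FALSE
  cl_fit <- fit_conditional_logit(data, cl_spec, options)
  K <- length(mm$beta_names)
  theta0 <- c(cl_fit$estimate[seq_len(K + 1L)], 0.1,
              cl_fit$estimate[K + 1L + seq_len(length(mm$w_names))])
  fn_gr <- function(th) rpl_core(th, mm, Z)
  opt <- maximize_bfgs(unname(theta0), fn_gr,
                       tol = options$tol %||% 1e-6,
                       maxit = options$maxit %||% 500L)
  if (!opt$converged) {
    warning("RPL did not reach gradient tolerance (|g| = ",
            format(opt$grad_norm, digits = 3), ")")
  }
  par_names <- theta_names(mm, random = TRUE)
  warn_separation(opt$theta, par_names)
  V <- covariance_from_hessian(opt$hessian, par_names)
  if (opt$theta[K + 2L] < 0) {
    # sign flip of sigma leaves the likelihood unchanged; report it
    # nonnegative and reflect the covariance accordingly
    opt$theta[K + 2L] <- -opt$theta[K + 2L]
    V[K + 2L, ] <- -V[K + 2L, ]
    V[, K + 2L] <- -V[, K + 2L]
  }
  new_dce_fit("RPL", spec, mm, opt, V, mm$n_resp, nrow(data$tasks),
              draws_used = draws$R, seed = draws$seed, random = TRUE)
}

#' @export
print.dce_fit <- function(x, ...) {
  cat(x$model_kind, "fit:", x$n_choices, "tasks,", x$n_respondents,
      "respondents\n")
  cat("  loglik:", format(x$loglik, digits = 8),
      " BIC:", format(x$bic, digits = 8), " k:", x$k, "\n")
  if (x$draws_used > 0) cat("  draws per respondent:", x$draws_used, "\n")
  cat("  converged:", x$converged, " (|gradient| =",
      format(x$grad_norm, digits = 3), ")\n")
  print(utils::head(coef_table(x), 12L))
  if (length(x$estimate) > 12L) cat("  ... (", length(x$estimate), "parameters )\n")
  invisible(x)
}

significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
      labels = c("***", "**", "*", ".", ""))
}

#' Coefficient table of a fitted model
#'
#' @param fit a \code{dce_fit}.
#' @return data.frame with estimate, SE, z, two-tailed p and significance
#'   stars (codes: . < 0.1, * < 0.05, ** < 0.01, *** < 0.001).
#' @export
coef_table <- function(fit) {
  z <- fit$estimate / fit$se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(parameter = fit$par_names, estimate = unname(fit$estimate),
             se = unname(fit$se), z = unname(z), p = unname(p),
             stars = as.character(significance_stars(p)),
             stringsAsFactors = FALSE)
}

#' Serialize an estimation result to a JSON report
#'
#' @param fit a \code{dce_fit} or \code{lcl_fit}.
#' @param path output path (\code{.json}).
#' @export
write_fit_report <- function(fit, path) {
  rep <- if (inherits(fit, "lcl_fit")) {
    list(model = "LCL", n_classes = fit$Q,
         loglik = fit$loglik, bic = fit$bic, k = fit$k,
         n_choices = fit$n_choices, n_respondents = fit$n_respondents,
         converged = fit$converged, iterations = fit$iterations,
         expected_class_shares = fit$expected_shares,
         parameters = lcl_coef_table(fit))
  } else {
    list(model = fit$model_kind, loglik = fit$loglik, bic = fit$bic,
         k = fit$k, n_choices = fit$n_choices,
         n_respondents = fit$n_respondents, draws = fit$draws_used,
         seed = fit$seed, converged = fit$converged,
         parameters = coef_table(fit))
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Rank fitted models by BIC
#'
#' All results must come from the same dataset (equal numbers of choice
#' tasks); they are sorted by ascending BIC and the minimum is flagged as
#' selected.
#'
#' @param results list of \code{dce_fit} / \code{lcl_fit} objects.
#' @return data.frame with model, loglik, k, bic, selected.
#' @export
model_selection <- function(results) {
  if (!length(results)) stop("no results to rank")
  n <- vapply(results, function(r) r$n_choices, 0)
  if (length(unique(n)) != 1L) {
    stop("results were fitted on different numbers of choices: ",
         paste(unique(n), collapse = ", "))
  }
  labels <- names(results) %||% vapply(results, function(r) {
    if (inherits(r, "lcl_fit")) paste0("LCL_Q", r$Q) else r$model_kind
  }, "")
  if (is.null(names(results)) || any(names(results) == "")) {
    labels <- make.unique(labels)
  }
  tab <- data.frame(model = labels,
                    loglik = vapply(results, function(r) r$loglik, 0),
                    k = vapply(results, function(r) r$k, 0),
                    bic = vapply(results, function(r) r$bic, 0),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$bic, tab$k), ]
  tab$selected <- seq_len(nrow(tab)) == 1L
  rownames(tab) <- NULL
  tab
}

#' Wrap a coefficient set as a fit object
#'
#' Builds a \code{dce_fit} directly from a \code{\link{parameters}} bundle so
#' post-estimation transforms (\code{\link{wtp}}, \code{\link{odds_ratios}},
#' \code{\link{scenario_curves}}) can be applied to externally supplied
#' coefficient sets (e.g. published point estimates). No data are attached:
#' the covariance is zero, so standard errors and significance are not
#' meaningful on such an object.
#'
#' @param params a \code{\link{parameters}} object.
#' @param spec the matching \code{\link{model_spec}}.
#' @param model_kind \code{"CL"} or \code{"RPL"}; defaults from
#'   \code{spec$optout_random}.
#' @return A \code{dce_fit} with \code{loglik}, \code{bic} set to \code{NA}.
#' @export
manual_fit <- function(params, spec,
                       model_kind = if (spec$optout_random) "RPL" else "CL") {
  validate_parameters(params, spec)
  random <- model_kind == "RPL"
  par_names <- c(attribute_column_names(spec), interaction_column_names(spec),
                 "optout_constant", if (random) "optout_sd",
                 spec$optout_covariates)
  est <- stats::setNames(
    c(params$beta, params$pi, params$delta_o,
      if (random) params$sigma_o, params$gamma), par_names)
  k <- length(est)
  V <- matrix(0, k, k, dimnames = list(par_names, par_names))
  structure(list(model_kind = model_kind, spec = spec, params = params,
                 estimate = est, par_names = par_names,
                 loglik = NA_real_, bic = NA_real_,
                 covariance = V, se = rep(0, k), k = k,
                 n_respondents = 0L, n_choices = 0L, draws_used = 0L,
                 seed = NA_integer_, converged = NA, iterations = 0L,
                 grad_norm = NA_real_),
            class = "dce_fit")
}
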