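# Latent-class conditional logit, estimated by EM.
#
# Within a class the vaccine utilities are x'(beta_q + Pi_q w) and the opt-out
# utility is a free class-specific constant delta_q (no covariates in the
# opt-out index; the covariates act on class membership instead). Class
# membership follows a multinomial logit in respondent covariates with class 1
# as reference (gamma_1 = 0).

# Per-respondent log-likelihood under one class parameter vector.
class_resp_loglik <- function(theta_q, mm) {
  K <- length(mm$beta_names)
  bp <- theta_q[seq_len(K)]
  delta <- theta_q[K + 1L]
  uA <- drop(mm$XA %*% bp)
  uB <- drop(mm$XB %*% bp)
  uO <- rep(delta, length(uA))
  m <- pmax(uA, uB, uO)
  den <- exp(uA - m) + exp(uB - m) + exp(uO - m)
  u_ch <- cbind(uA, uB, uO)[cbind(seq_along(uA), mm$chosen)]
  drop(rowsum((u_ch - m) - log(den), mm$resp))
}

# Membership log-probabilities: n_resp x Q matrix of log pi_iq.
membership_logprob <- function(gamma_mat, WR1) {
  eta <- WR1 %*% t(rbind(0, gamma_mat))  # class 1 reference
  eta - row_logsumexp(eta)
}

# Weighted multinomial-logit M-step: maximise sum_iq h_iq log pi_iq(gamma).
fit_membership <- function(h, WR1, gamma0, maxit = 200L) {
  Q <- ncol(h)
  kc <- ncol(WR1)
  obj <- function(g) {
    gm <- matrix(g, Q - 1L, kc)
    -sum(h * membership_logprob(gm, WR1))
  }
  grd <- function(g) {
    gm <- matrix(g, Q - 1L, kc)
    P <- exp(membership_logprob(gm, WR1))
    -as.vector(t(crossprod(WR1, (h - P)[, -1L, drop = FALSE])))
  }
  opt <- stats::optim(as.vector(gamma0), obj, grd, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  matrix(opt$par, Q - 1L, kc)
}

# Weighted conditional-logit M-step for one class (respondent weights
# expanded to tasks), warm-started.
fit_class_params <- function(theta0, mm, task_w, maxit = 100L) {
  fn <- function(th) -cl_core(th, mm, weights = task_w)$loglik
  gr <- function(th) -cl_core(th, mm, weights = task_w)$gradient
  stats::optim(theta0, fn, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-13))$par
}

pack_lcl <- function(theta_classes, gamma_mat) {
  c(unlist(theta_classes), if (!is.null(gamma_mat)) as.vector(gamma_mat))
}

# Observed-data log-likelihood and analytic score of the full LCL parameter
# vector (Fisher identity: posterior-weighted complete-data score).
lcl_obs_loglik <- function(theta_all, mm, WR1, Q) {
  K <- length(mm$beta_names) + 1L
  theta_classes <- lapply(seq_len(Q), function(q) {
    theta_all[(q - 1L) * K + seq_len(K)]
  })
  gamma_mat <- if (Q > 1L) {
    matrix(theta_all[Q * K + seq_len((Q - 1L) * ncol(WR1))], Q - 1L, ncol(WR1))
  } else NULL
  LL <- vapply(theta_classes, class_resp_loglik, numeric(mm$n_resp), mm = mm)
  lp <- if (Q > 1L) membership_logprob(gamma_mat, WR1) else matrix(0, mm$n_resp, 1L)
  lj <- lp + LL
  li <- row_logsumexp(lj)
  h <- exp(lj - li)
  grad_classes <- lapply(seq_len(Q), function(q) {
    cl_core(theta_classes[[q]], mm, weights = h[mm$resp, q])$gradient
  })
  grad_gamma <- if (Q > 1L) {
    P <- exp(lp)
    as.vector(t(crossprod(WR1, (h - P)[, -1L, drop = FALSE])))
  } else NULL
  list(loglik = sum(li), gradient = c(unlist(grad_classes), grad_gamma),
       posterior = h, LL = LL, lp = lp)
}

#' Fit the latent-class conditional logit by EM
#'
#' The E-step computes posterior class responsibilities proportional to
#' \eqn{\pi_{iq} \prod_t P(y_{it} \mid \theta_q)}; the M-step solves one
#' weighted conditional-logit problem per class and a weighted
#' multinomial-logit class-membership problem (class 1 as reference). The
#' best of \code{n_starts} seeded random initialisations is retained; ties
#' are broken by the lowest start index. The observed-data log-likelihood is
#' checked to be nondecreasing across iterations.
#'
#' @param data a \code{\link{dce_data}}.
#' @param spec a \code{\link{model_spec}}; \code{spec$class_covariates} feed
#'   the membership model.
#' @param Q number of classes (default \code{spec$n_classes}).
#' @param n_starts random initialisations (default 10).
#' @param seed integer seed for the initial responsibilities.
#' @param options list; \code{tol} (relative log-likelihood change, default
#'   1e-8), \code{maxit} (default 2000), \code{se} (compute standard errors,
#'   default TRUE).
#' @return An object of class \code{lcl_fit}.
#' @export
em_fit_lcl <- function(data, spec, Q = spec$n_classes, n_starts = 10L,
                       seed = 1L, options = list()) {
  Q <- as.integer(Q)
  if (Q < 1L) stop("Q must be >= 1")
  tol <- options$tol %||% 1e-8
  maxit <- options$maxit %||% 2000L
  mm <- build_model_matrices(data, spec, optout_covariates = character(0))
  WR1 <- if (Q > 1L) {
    resp_df <- data$respondents
    cbind(constant = 1,
          vapply(stats::setNames(spec$class_covariates, spec$class_covariates),
                 function(nm) covariate_scaled(resp_df, nm),
                 numeric(nrow(resp_df))))
  } else matrix(1, mm$n_resp, 1L)
  K <- length(mm$beta_names) + 1L

  run_start <- function(s) {
    h <- withr_seed(seed + 1000L * s,
                    matrix(stats::rexp(mm$n_resp * Q), mm$n_resp, Q))
    h <- h / rowSums(h)
    theta_classes <- replicate(Q, rep(0, K), simplify = FALSE)
    gamma_mat <- if (Q > 1L) matrix(0, Q - 1L, ncol(WR1)) else NULL
    ll_prev <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(maxit)) {
      # M-step
      for (q in seq_len(Q)) {
        theta_classes[[q]] <- fit_class_params(theta_classes[[q]], mm,
                                               h[mm$resp, q],
                                               maxit = if (it == 1L) 200L else 60L)
      }
      if (Q > 1L) gamma_mat <- fit_membership(h, WR1, gamma_mat)
      # E-step / observed loglik
      LL <- vapply(theta_classes, class_resp_loglik, numeric(mm$n_resp), mm = mm)
      lp <- if (Q > 1L) membership_logprob(gamma_mat, WR1) else matrix(0, mm$n_resp, 1L)
      lj <- lp + LL
      li <- row_logsumexp(lj)
      h <- exp(lj - li)
      ll <- sum(li)
      trace <- c(trace, ll)
      if (ll < ll_prev - 1e-8 * max(1, abs(ll))) {
        stop("EM log-likelihood decreased (", ll_prev, " -> ", ll, ")")
      }
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * abs(ll_prev)) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
    }
    list(loglik = ll, theta_classes = theta_classes, gamma_mat = gamma_mat,
         posterior = h, trace = trace, converged = converged,
         iterations = length(trace))
  }

  starts <- lapply(seq_len(max(1L, n_starts)), run_start)
  lls <- vapply(starts, function(s) s$loglik, 0)
  best <- starts[[which.max(lls)]]
  if (!all(vapply(starts, function(s) s$converged, TRUE))) {
    warning(sum(!vapply(starts, function(s) s$converged, TRUE)),
            " EM start(s) did not converge within maxit")
  }
  shares <- colMeans(best$posterior)
  if (any(shares < 0.005)) {
    warning("expected class share below 0.5%; Q may exceed what the data support")
  }
  theta_all <- pack_lcl(best$theta_classes, best$gamma_mat)
  k <- length(theta_all)
  n_choices <- nrow(data$tasks)
  V <- NULL
  se <- rep(NA_real_, k)
  par_names <- c(unlist(lapply(seq_len(Q), function(q) {
    paste0("class", q, ".", c(mm$beta_names, "optout_constant"))
  })), if (Q > 1L) as.vector(t(outer(seq(2L, Q), colnames(WR1),
                                     function(q, v) paste0("class", q, ".", v)))))
  if (isTRUE(options$se %||% TRUE)) {
    fn_gr <- function(th) lcl_obs_loglik(th, mm, WR1, Q)
    H <- gradient_hessian(theta_all, fn_gr)
    V <- covariance_from_hessian(H, par_names)
    se <- sqrt(pmax(diag(V), 0))
  }
  structure(list(
    Q = Q, spec = spec, mm_beta_names = mm$beta_names,
    class_params = lapply(best$theta_classes, function(th) {
      list(beta_pi = stats::setNames(th[seq_len(K - 1L)], mm$beta_names),
           delta_o = th[K])
    }),
    class_gamma = if (Q > 1L) {
      gm <- best$gamma_mat
      dimnames(gm) <- list(paste0("class", seq(2L, Q)), colnames(WR1))
      gm
    } else NULL,
    class_covariates = if (Q > 1L) spec$class_covariates else character(0),
    posterior = best$posterior,
    expected_shares = shares,
    theta = stats::setNames(theta_all, par_names), par_names = par_names,
    loglik = best$loglik, bic = -2 * best$loglik + k * log(n_choices),
    k = k, n_choices = n_choices, n_respondents = mm$n_resp,
    covariance = V, se = stats::setNames(se, par_names),
    converged = best$converged, iterations = best$iterations,
    loglik_trace = best$trace, seed = seed, n_starts = n_starts
  ), class = "lcl_fit")
}

#' @export
print.lcl_fit <- function(x, ...) {
  cat("Latent-class conditional logit (Q =", x$Q, "):",
      x$n_choices, "tasks,", x$n_respondents, "respondents\n")
  cat("  loglik:", format(x$loglik, digits = 8),
      " BIC:", format(x$bic, digits = 8), " k:", x$k, "\n")
  cat("  expected class shares:",
      paste(sprintf("%.2f%%", 100 * x$expected_shares), collapse = ", "), "\n")
  cat("  EM iterations:", x$iterations, " converged:", x$converged, "\n")
  invisible(x)
}

#' Coefficient table of a latent-class fit
#'
#' @param fit an \code{lcl_fit}.
#' @return data.frame with parameter, estimate, SE, z, p, stars.
#' @export
lcl_coef_table <- function(fit) {
  z <- fit$theta / fit$se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(parameter = fit$par_names, estimate = unname(fit$theta),
             se = unname(fit$se), z = unname(z), p = unname(p),
             stars = as.character(significance_stars(p)),
             stringsAsFactors = FALSE)
}
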