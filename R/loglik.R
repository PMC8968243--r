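# Likelihood machinery for the conditional logit and the panel mixed logit
# with a random opt-out constant.
#
# Parameter packing used by all optimisers:
#   theta = c(beta+pi block, delta_o, [sigma_raw], gamma)
# sigma is parametrised unconstrained (the likelihood depends on |sigma| only)
# and reported as its absolute value.

pack_theta <- function(params, random) {
  c(params$beta, params$pi, params$delta_o,
    if (random) params$sigma_o, params$gamma)
}

unpack_theta <- function(theta, mm, random) {
  K <- length(mm$beta_names)
  Kw <- length(mm$w_names)
  nb <- mm$beta_names
  n_inter <- sum(grepl("_x_", nb))
  beta <- stats::setNames(theta[seq_len(K - n_inter)], nb[seq_len(K - n_inter)])
  pi <- stats::setNames(theta[seq_len(n_inter) + (K - n_inter)],
                        nb[seq_len(n_inter) + (K - n_inter)])
  delta <- theta[K + 1L]
  sigma <- if (random) abs(theta[K + 2L]) else 0
  gamma <- stats::setNames(theta[K + (if (random) 3L else 2L) - 1L + seq_len(Kw)],
                           mm$w_names)
  parameters(beta = beta, pi = pi, delta_o = delta, sigma_o = sigma,
             gamma = gamma)
}

theta_names <- function(mm, random) {
  c(mm$beta_names, "optout_constant",
    if (random) "optout_sd", mm$w_names)
}

# Conditional-logit log-likelihood with exact analytic gradient.
# `weights` are per-task weights (EM responsibilities expanded to tasks).
cl_core <- function(theta, mm, weights = NULL) {
  K <- length(mm$beta_names)
  Kw <- ncol(mm$W)
  bp <- theta[seq_len(K)]
  delta <- theta[K + 1L]
  gamma <- if (Kw) theta[K + 1L + seq_len(Kw)] else numeric(0)
  uA <- drop(mm$XA %*% bp)
  uB <- drop(mm$XB %*% bp)
  uO <- delta + (if (Kw) drop(mm$W %*% gamma) else 0)
  m <- pmax(uA, uB, uO)
  eA <- exp(uA - m); eB <- exp(uB - m); eO <- exp(uO - m)
  den <- eA + eB + eO
  u_ch <- cbind(uA, uB, uO)[cbind(seq_along(uA), mm$chosen)]
  lp <- (u_ch - m) - log(den)
  w <- weights %||% rep(1, length(lp))
  PA <- eA / den; PB <- eB / den; PO <- eO / den
  rA <- w * ((mm$chosen == 1L) - PA)
  rB <- w * ((mm$chosen == 2L) - PB)
  rO <- w * ((mm$chosen == 3L) - PO)
  grad <- c(drop(crossprod(mm$XA, rA)) + drop(crossprod(mm$XB, rB)),
            sum(rO),
            if (Kw) drop(crossprod(mm$W, rO)))
  list(loglik = sum(w * lp), gradient = grad)
}

#' Conditional-logit log-likelihood and analytic gradient
#'
#' Sum over tasks of the log probability of the chosen alternative under the
#' fixed-constant conditional logit (each task treated as a pseudo-individual).
#' The opt-out standard deviation in \code{params} is ignored.
#'
#' @param params a \code{\link{parameters}} object.
#' @param data a \code{\link{dce_data}}.
#' @param spec a \code{\link{model_spec}}.
#' @return Scalar log-likelihood with attribute \code{"gradient"} (exact
#'   analytic, ordered as beta/pi, opt-out constant, gamma).
#' @export
cl_loglik <- function(params, data, spec) {
  mm <- build_model_matrices(data, spec)
  validate_parameters(params, spec)
  res <- cl_core(pack_theta(params, random = FALSE), mm)
  structure(res$loglik, gradient = res$gradient)
}

# Panel mixed-logit simulated log-likelihood with analytic gradient.
# For respondent i: L_i = (1/R) sum_r prod_t P(chosen_it | delta_ir),
# delta_ir = delta_o + sigma * z_ir; the product over the respondent's tasks
# sits inside the draw average (panel structure).
rpl_core <- function(theta, mm, Z, weights_resp = NULL) {
  K <- length(mm$beta_names)
  Kw <- ncol(mm$W)
  bp <- theta[seq_len(K)]
  delta <- theta[K + 1L]
  sigma <- theta[K + 2L]
  gamma <- if (Kw) theta[K + 2L + seq_len(Kw)] else numeric(0)
  R <- ncol(Z)
  uA <- drop(mm$XA %*% bp)
  uB <- drop(mm$XB %*% bp)
  uO0 <- delta + (if (Kw) drop(mm$W %*% gamma) else 0)
  Zt <- Z[mm$resp, , drop = FALSE]            # n_tasks x R
  UO <- uO0 + sigma * Zt
  M <- pmax(uA, uB, UO)
  eA <- exp(uA - M); eB <- exp(uB - M); eO <- exp(UO - M)
  den <- eA + eB + eO
  is_A <- mm$chosen == 1L; is_B <- mm$chosen == 2L; is_O <- mm$chosen == 3L
  Uch <- UO
  Uch[is_A, ] <- uA[is_A]
  Uch[is_B, ] <- uB[is_B]
  lp <- (Uch - M) - log(den)                  # n_tasks x R
  ll_ir <- rowsum(lp, mm$resp)                # n_resp x R
  li <- row_logsumexp(ll_ir) - log(R)
  wr <- weights_resp %||% rep(1, mm$n_resp)
  loglik <- sum(wr * li)
  # draw weights w_ir = exp(ll_ir - li)/R, rows sum to 1
  Wir <- exp(ll_ir - (li + log(R)))
  Wt <- (wr * Wir)[mm$resp, , drop = FALSE]   # n_tasks x R
  PA <- eA / den; PB <- eB / den; PO <- eO / den
  MA <- rowSums(Wt * (is_A - PA))
  MB <- rowSums(Wt * (is_B - PB))
  RO <- Wt * (is_O - PO)
  MO <- rowSums(RO)
  grad <- c(drop(crossprod(mm$XA, MA)) + drop(crossprod(mm$XB, MB)),
            sum(MO),
            sum(RO * Zt),
            if (Kw) drop(crossprod(mm$W, MO)))
  list(loglik = loglik, gradient = grad)
}

#' Simulated log-likelihood of the panel random-parameter logit
#'
#' Evaluates \eqn{\sum_i \log\{ R^{-1} \sum_r \prod_t P(y_{it} \mid
#' \delta_{ir})\}} with \eqn{\delta_{ir} = \delta_o + \sigma_o z_{ir}}, the
#' draw blocks \eqn{z_{ir}} coming from \code{draws}. The product over a
#' respondent's tasks is taken inside the draw average, so the panel
#' correlation induced by the shared random opt-out constant is respected.
#'
#' @param params a \code{\link{parameters}} object (with \code{sigma_o >= 0}).
#' @param data a \code{\link{dce_data}}.
#' @param spec a \code{\link{model_spec}}.
#' @param draws a \code{\link{draw_set}} with one block per respondent.
#' @return Scalar simulated log-likelihood with attribute \code{"gradient"}.
#' @export
rpl_simulated_loglik <- function(params, data, spec, draws) {
  validate_parameters(params, spec)
  mm <- build_model_matrices(data, spec)
  if (nrow(draws$values) < mm$n_resp) {
    stop("draw set has fewer blocks than respondents")
  }
  Z <- draws$values[seq_len(mm$n_resp), , drop = FALSE]
  res <- rpl_core(pack_theta(params, random = TRUE), mm, Z)
  structure(res$loglik, gradient = res$gradient)
}
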