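#' @keywords internal
"_PACKAGE"

# Row-wise log-sum-exp, overflow safe. `x` is a matrix; returns a vector.
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Radical-inverse Halton sequence in a given prime base.
halton_sequence <- function(n, base = 3L, skip = 10L) {
  idx <- seq_len(n) + skip
  out <- numeric(n)
  f <- 1 / base
  i <- idx
  while (any(i > 0L)) {
    out <- out + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  out
}

#' Standard-normal draw blocks for maximum simulated likelihood
#'
#' Generates one block of \code{R} standard-normal deviates per respondent,
#' reused across that respondent's choice tasks so the random opt-out constant
#' is held fixed within a panel. Halton draws (base 3, first 10 points
#' discarded) are the default low-discrepancy scheme; \code{"pseudo_random"}
#' uses seeded \code{rnorm} draws.
#'
#' @param n_resp number of respondents.
#' @param R draws per respondent (>= 1).
#' @param scheme \code{"halton"} or \code{"pseudo_random"}.
#' @param seed integer seed; for the deterministic Halton scheme it is recorded
#'   but does not alter the sequence.
#' @return An object of class \code{draw_set}: list with \code{values}
#'   (\code{n_resp x R} matrix), \code{R}, \code{scheme}, \code{seed}.
#' @export
draw_set <- function(n_resp, R = 500L, scheme = c("halton", "pseudo_random"),
                     seed = 1L) {
  scheme <- match.arg(scheme)
  if (R < 1L) stop("R must be >= 1")
  if (n_resp < 1L) stop("n_resp must be >= 1")
  if (scheme == "halton") {
    u <- halton_sequence(n_resp * R, base = 3L, skip = 10L)
    z <- stats::qnorm(u)
    values <- matrix(z, nrow = n_resp, ncol = R, byrow = TRUE)
  } else {
    values <- withr_seed(seed, matrix(stats::rnorm(n_resp * R), n_resp, R))
  }
  structure(list(values = values, R = as.integer(R), scheme = scheme,
                 seed = as.integer(seed)),
            class = "draw_set")
}

# Evaluate `expr` under a local RNG seed without disturbing the global stream.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Gauss-Hermite nodes/weights rescaled for an N(mu, sd^2) expectation:
# E[f(X)] ~ sum w_k f(mu + sqrt(2) sd x_k) / sqrt(pi).
gauss_hermite_normal <- function(order, mean = 0, sd = 1) {
  gh <- pracma::gaussHermite(order)
  list(nodes = mean + sqrt(2) * sd * gh$x, weights = gh$w / sqrt(pi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
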