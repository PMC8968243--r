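#' Construct and validate a vaccine profile
#'
#' One alternative's attribute bundle: out-of-pocket cost in US$, effectiveness
#' in percent, days for antibodies to develop, months of protection, mild side
#' effects per 10 persons, severe side effects per 1,000,000 persons, the
#' recommending body, country of origin, and months since successful clinical
#' trials.
#'
#' @param cost US$ out-of-pocket, >= 0.
#' @param effectiveness percent in [0, 100].
#' @param incubation days for antibodies to develop, > 0.
#' @param protection months of protection, > 0.
#' @param mild persons out of 10 with mild side effects, in [0, 10].
#' @param severe persons out of 1,000,000 with severe side effects, in [0, 1e6].
#' @param recommender one of PCP, CDC, WHO, Media.
#' @param origin one of Germany, USA, UK, China.
#' @param introduced months since successful clinical trials, >= 0.
#' @return A named list of class \code{vaccine_profile}.
#' @export
vaccine_profile <- function(cost, effectiveness, incubation, protection,
                            mild, severe, recommender, origin, introduced) {
  p <- list(cost = cost, effectiveness = effectiveness,
            incubation = incubation, protection = protection,
            mild = mild, severe = severe,
            recommender = as.character(recommender),
            origin = as.character(origin), introduced = introduced)
  validate_profile(p)
  structure(p, class = "vaccine_profile")
}

validate_profile <- function(p) {
  if (p$cost < 0) stop("invalid vaccine profile field 'cost': must be >= 0")
  if (p$effectiveness < 0 || p$effectiveness > 100) {
    stop("invalid vaccine profile field 'effectiveness': must be in [0, 100]")
  }
  if (p$mild < 0 || p$mild > 10) {
    stop("invalid vaccine profile field 'mild': must be in [0, 10]")
  }
  if (p$severe < 0 || p$severe > 1e6) {
    stop("invalid vaccine profile field 'severe': must be in [0, 1e6]")
  }
  if (!p$recommender %in% VACCINE_LEVELS$recommender) {
    stop("invalid vaccine profile field 'recommender': unknown level '",
         p$recommender, "'")
  }
  if (!p$origin %in% VACCINE_LEVELS$origin) {
    stop("invalid vaccine profile field 'origin': unknown level '", p$origin, "'")
  }
  invisible(p)
}

#' Construct a respondent covariate record
#'
#' All unspecified flags default to 0; \code{high_income} is derived from
#' \code{household_income} (>= $120,000) unless given explicitly.
#'
#' @param id respondent identifier.
#' @param ... covariate values; see \code{RESPONDENT_FIELDS} in the package
#'   source for the recognised names (male, household_income, age, bmi,
#'   wave2, against_vaccination, ...).
#' @return A one-row \code{data.frame} with all recognised covariates.
#' @export
respondent <- function(id = 1L, ...) {
  vals <- list(...)
  bad <- setdiff(names(vals), RESPONDENT_FIELDS)
  if (length(bad)) stop("unknown respondent field: ", paste(bad, collapse = ", "))
  out <- as.list(stats::setNames(rep(0, length(RESPONDENT_FIELDS)),
                                 RESPONDENT_FIELDS))
  out$age <- vals$age %||% 42
  out$bmi <- vals$bmi %||% 31
  out$household_income <- vals$household_income %||% 62236
  for (nm in names(vals)) out[[nm]] <- vals[[nm]]
  if (is.null(vals$high_income)) {
    out$high_income <- as.numeric(out$household_income >= 120000)
  }
  if (out$age <= 0) stop("respondent age must be > 0")
  if (out$bmi <= 0) stop("respondent bmi must be > 0")
  if (out$democrat == 1 && out$republican == 1) {
    stop("respondent cannot be both democrat and republican")
  }
  cbind(data.frame(resp_id = id), as.data.frame(out))
}

# Covariate on the scale used inside index functions: income in $10K units.
covariate_scaled <- function(respondents, name) {
  v <- respondents[[name]]
  if (is.null(v)) stop("missing covariate: ", name)
  if (name == "household_income") v / 1e4 else as.numeric(v)
}

#' Encode one vaccine alternative into its utility design vector
#'
#' Produces the ordered numeric attribute vector entering the vaccine utility:
#' an optional free-vaccine dummy (\code{1[cost == 0]}, only under
#' \code{cost_mode = "linear_plus_free"}), the seven continuous attributes in
#' their printed units, origin dummies (base Germany), recommender dummies
#' (base PCP), and the observed-heterogeneity interaction columns (attribute
#' value times respondent covariate).
#'
#' @param profile a \code{\link{vaccine_profile}} (or coercible named list).
#' @param resp a one-row respondent record (see \code{\link{respondent}}).
#' @param spec a \code{\link{model_spec}}.
#' @return Named numeric vector.
#' @export
encode_vaccine <- function(profile, resp, spec) {
  validate_profile(profile)
  base <- c(
    if (spec$cost_mode == "linear_plus_free") c(free = as.numeric(profile$cost == 0)),
    cost = profile$cost,
    effectiveness = profile$effectiveness,
    protection = profile$protection,
    incubation = profile$incubation,
    severe = profile$severe,
    mild = profile$mild,
    introduced = profile$introduced,
    stats::setNames(as.numeric(profile$origin == ORIGIN_DUMMIES),
                    paste0("origin_", ORIGIN_DUMMIES)),
    stats::setNames(as.numeric(profile$recommender == RECOMMENDER_DUMMIES),
                    paste0("rec_", RECOMMENDER_DUMMIES))
  )
  inter <- vapply(spec$interactions, function(pair) {
    if (!pair[1] %in% names(base)) {
      stop("interaction attribute column not in encoding: ", pair[1])
    }
    base[[pair[1]]] * covariate_scaled(resp, pair[2])
  }, 0)
  names(inter) <- interaction_column_names(spec)
  c(base, inter)
}

#' Encode the opt-out index covariate vector
#'
#' Returns the respondent covariates of the opt-out ("no vaccine") index
#' function, in the order declared by the model specification and on the
#' documented scales: household income in $10,000 units, age in years, BMI in
#' kg/m^2, all indicator covariates 0/1.
#'
#' @param resp one-row respondent record.
#' @param spec a \code{\link{model_spec}}.
#' @return Named numeric vector over \code{spec$optout_covariates}.
#' @export
encode_optout <- function(resp, spec) {
  vapply(stats::setNames(spec$optout_covariates, spec$optout_covariates),
         function(nm) covariate_scaled(resp, nm), 0)
}

#' Choice probabilities for one task
#'
#' Computes the logit probability triple over \{vaccine A, vaccine B, opt out\}
#' for a single choice task. Vaccine utilities are linear in the encoded
#' attribute vector; the opt-out utility is \code{delta_i + w'gamma}, where
#' \code{delta_i} is the (possibly random-effect) opt-out constant realisation.
#' The softmax is computed after subtracting the maximum utility, so it is
#' overflow safe.
#'
#' @param params a \code{\link{parameters}} object.
#' @param task list with elements \code{alternative_A} and \code{alternative_B}
#'   (vaccine profiles).
#' @param resp one-row respondent record.
#' @param spec a \code{\link{model_spec}}.
#' @param delta_i realisation of the opt-out constant; defaults to its mean
#'   \code{params$delta_o}.
#' @return Numeric vector \code{c(A =, B =, optout =)} summing to 1.
#' @export
choice_probabilities <- function(params, task, resp, spec,
                                 delta_i = params$delta_o) {
  if (!is.finite(delta_i)) stop("delta_i must be finite")
  bp <- c(params$beta, params$pi)
  xA <- encode_vaccine(task$alternative_A, resp, spec)
  xB <- encode_vaccine(task$alternative_B, resp, spec)
  stopifnot(length(bp) == length(xA))
  w <- encode_optout(resp, spec)
  u <- c(A = sum(xA * bp), B = sum(xB * bp),
         optout = delta_i + sum(w * params$gamma))
  if (any(!is.finite(u))) stop("non-finite utility")
  e <- exp(u - max(u))
  e / sum(e)
}

#' Parameter bundle for the conditional / random-parameter logit
#'
#' @param beta named attribute coefficients, in the order of
#'   \code{encode_vaccine}'s base columns (including \code{free} when the spec
#'   uses \code{linear_plus_free}).
#' @param pi named interaction coefficients matching the spec's interactions.
#' @param delta_o opt-out constant mean.
#' @param sigma_o opt-out constant standard deviation (>= 0; 0 for non-random
#'   models).
#' @param gamma named opt-out index coefficients over the spec's
#'   \code{optout_covariates}.
#' @param spec optional \code{\link{model_spec}}; when supplied, block lengths
#'   and names are validated against it.
#' @return Object of class \code{parameters}.
#' @export
parameters <- function(beta, pi = numeric(0), delta_o = 0, sigma_o = 0,
                       gamma = numeric(0), spec = NULL) {
  if (sigma_o < 0) stop("sigma_o must be >= 0")
  p <- structure(list(beta = beta, pi = pi, delta_o = delta_o,
                      sigma_o = sigma_o, gamma = gamma),
                 class = "parameters")
  if (!is.null(spec)) validate_parameters(p, spec)
  p
}

validate_parameters <- function(params, spec) {
  an <- attribute_column_names(spec)
  if (length(params$beta) != length(an)) {
    stop("beta block: expected ", length(an), " coefficients (",
         paste(an, collapse = ", "), "), got ", length(params$beta))
  }
  if (length(params$pi) != length(spec$interactions)) {
    stop("pi block: expected ", length(spec$interactions), " coefficients")
  }
  if (length(params$gamma) != length(spec$optout_covariates)) {
    stop("gamma block: expected ", length(spec$optout_covariates),
         " coefficients")
  }
  if (params$sigma_o < 0) stop("sigma_o must be >= 0")
  invisible(params)
}

# ---- vectorised encodings over a whole dataset (internal workhorses) -----

# Encode all tasks of a dce_data object at once. Returns XA, XB
# (n_tasks x K attribute+interaction columns), W (n_tasks x K_w opt-out
# covariates), chosen (1 = A, 2 = B, 3 = opt out), resp (respondent index per
# task), and column names.
build_model_matrices <- function(data, spec,
                                 optout_covariates = spec$optout_covariates) {
  tasks <- data$tasks
  resp_df <- data$respondents[match(tasks$resp_id, data$respondents$resp_id), ,
                              drop = FALSE]
  encode_side <- function(prefix) {
    g <- function(nm) tasks[[paste0(prefix, "_", nm)]]
    cols <- list()
    if (spec$cost_mode == "linear_plus_free") cols$free <- as.numeric(g("cost") == 0)
    cols$cost <- g("cost")
    cols$effectiveness <- g("effectiveness")
    cols$protection <- g("protection")
    cols$incubation <- g("incubation")
    cols$severe <- g("severe")
    cols$mild <- g("mild")
    cols$introduced <- g("introduced")
    for (lv in ORIGIN_DUMMIES) cols[[paste0("origin_", lv)]] <- as.numeric(g("origin") == lv)
    for (lv in RECOMMENDER_DUMMIES) cols[[paste0("rec_", lv)]] <- as.numeric(g("recommender") == lv)
    X <- do.call(cbind, cols)
    for (i in seq_along(spec$interactions)) {
      pair <- spec$interactions[[i]]
      X <- cbind(X, X[, pair[1]] * covariate_scaled(resp_df, pair[2]))
    }
    colnames(X) <- c(names(cols), interaction_column_names(spec))
    X
  }
  W <- if (length(optout_covariates)) {
    do.call(cbind, lapply(stats::setNames(optout_covariates, optout_covariates),
                          function(nm) covariate_scaled(resp_df, nm)))
  } else {
    matrix(0, nrow(tasks), 0)
  }
  resp_ids <- unique(data$respondents$resp_id)
  list(XA = encode_side("a"), XB = encode_side("b"), W = W,
       chosen = match(tasks$chosen, c("A", "B", "optout")),
       resp = match(tasks$resp_id, resp_ids),
       n_resp = length(resp_ids), resp_ids = resp_ids,
       beta_names = c(attribute_column_names(spec),
                      interaction_column_names(spec)),
       w_names = optout_covariates)
}
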