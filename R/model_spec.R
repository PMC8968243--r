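# Canonical attribute / covariate vocabulary -------------------------------

# Experimental attributes of a vaccine alternative and their admissible levels.
# Continuous attributes list the design levels; encoding accepts any value in
# the stated domain so post-estimation scenarios can extrapolate (e.g. cost
# beyond the highest design level).
VACCINE_LEVELS <- list(
  cost          = c(0, 50, 100, 175),
  effectiveness = c(20, 40, 60, 80),
  incubation    = c(7, 14, 21),
  protection    = c(3, 6, 12),
  mild          = c(1, 3, 5),
  severe        = c(1, 10, 100),
  recommender   = c("PCP", "CDC", "WHO", "Media"),
  origin        = c("Germany", "USA", "UK", "China"),
  introduced    = c(3, 6)
)

ORIGIN_BASE <- "Germany"
RECOMMENDER_BASE <- "PCP"
ORIGIN_DUMMIES <- c("USA", "UK", "China")
RECOMMENDER_DUMMIES <- c("Media", "CDC", "WHO")

# Respondent covariates recognised throughout the package. household_income is
# in $/yr (scaled to $10K units wherever it enters an index function); age in
# years; bmi in kg/m^2; everything else 0/1.
RESPONDENT_FIELDS <- c(
  "male", "household_income", "high_income", "education_bsc",
  "education_postgrad", "age", "black", "hispanic", "asian",
  "religion_extreme", "democrat", "republican", "tested_covid", "had_covid",
  "no_insurance", "flu_shot", "against_vaccination", "older65_household",
  "bmi", "underlying_condition", "works_fulltime", "wave2"
)

# Default covariate order of the opt-out index function.
DEFAULT_OPTOUT_COVARIATES <- c(
  "male", "household_income", "education_bsc", "education_postgrad", "age",
  "black", "hispanic", "asian", "religion_extreme", "democrat",
  "tested_covid", "had_covid", "no_insurance", "flu_shot",
  "against_vaccination", "older65_household", "bmi",
  "underlying_condition", "works_fulltime"
)

# Class-membership model: same list minus hispanic (not informative for class
# assignment in this application).
DEFAULT_CLASS_COVARIATES <- setdiff(DEFAULT_OPTOUT_COVARIATES, "hispanic")

DEFAULT_INTERACTIONS <- list(
  c("cost", "high_income"),
  c("effectiveness", "wave2"),
  c("origin_China", "republican")
)

#' Model specification for the vaccine choice models
#'
#' Declares how raw choice records are turned into the utility design: the
#' cost specification (purely linear, or linear plus a separate free-vaccine
#' dummy), the observed-heterogeneity interactions entering the vaccine
#' utility, the covariates of the opt-out index, whether the opt-out constant
#' is a normally distributed random effect (panel mixed logit), and the number
#' of latent preference classes with their membership covariates.
#'
#' @param cost_mode \code{"linear"} (cost enters linearly) or
#'   \code{"linear_plus_free"} (additionally a dummy for a free vaccine,
#'   \code{1[cost == 0]}).
#' @param interactions list of character pairs \code{c(attribute_column,
#'   covariate)}; defaults to cost x high income, effectiveness x wave 2, and
#'   China origin x Republican.
#' @param optout_covariates ordered covariate names of the opt-out index.
#' @param optout_random logical; random (normal) opt-out constant.
#' @param n_classes number of latent classes Q (>= 1).
#' @param class_covariates covariate names of the multinomial-logit
#'   class-membership model (used when \code{n_classes > 1}).
#' @return An object of class \code{model_spec}.
#' @export
model_spec <- function(cost_mode = c("linear", "linear_plus_free"),
                       interactions = DEFAULT_INTERACTIONS,
                       optout_covariates = DEFAULT_OPTOUT_COVARIATES,
                       optout_random = FALSE,
                       n_classes = 1L,
                       class_covariates = DEFAULT_CLASS_COVARIATES) {
  cost_mode <- match.arg(cost_mode)
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L) stop("n_classes must be >= 1")
  for (pair in interactions) {
    if (length(pair) != 2L) stop("each interaction must be a (attribute, covariate) pair")
    if (!pair[2] %in% RESPONDENT_FIELDS) {
      stop("unknown interaction covariate: ", pair[2])
    }
  }
  bad <- setdiff(optout_covariates, RESPONDENT_FIELDS)
  if (length(bad)) stop("unknown opt-out covariate: ", paste(bad, collapse = ", "))
  bad <- setdiff(class_covariates, RESPONDENT_FIELDS)
  if (length(bad)) stop("unknown class covariate: ", paste(bad, collapse = ", "))
  structure(list(cost_mode = cost_mode,
                 interactions = interactions,
                 optout_covariates = optout_covariates,
                 optout_random = isTRUE(optout_random),
                 n_classes = n_classes,
                 class_covariates = class_covariates),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Vaccine choice model specification\n")
  cat("  cost:", x$cost_mode,
      if (x$cost_mode == "linear_plus_free") "(free-vaccine dummy + linear cost)" else "",
      "\n")
  cat("  interactions:",
      paste(vapply(x$interactions, paste, "", collapse = " x "), collapse = ", "),
      "\n")
  cat("  opt-out covariates:", length(x$optout_covariates),
      if (x$optout_random) "(random constant)" else "(fixed constant)", "\n")
  if (x$n_classes > 1L) {
    cat("  latent classes:", x$n_classes, "with",
        length(x$class_covariates), "membership covariates\n")
  }
  invisible(x)
}

#' Read a model specification from a YAML or JSON config file
#'
#' Recognised keys: \code{cost_mode}, \code{interactions} (list of two-element
#' lists), \code{optout_covariates}, \code{optout_random}, \code{n_classes},
#' \code{class_covariates}. Missing keys fall back to the defaults of
#' \code{\link{model_spec}}.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{model_spec}.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  inter <- cfg$interactions
  if (!is.null(inter)) {
    if (is.matrix(inter)) inter <- asplit(inter, 1L)
    inter <- lapply(inter, function(p) as.character(unlist(p)))
  }
  model_spec(
    cost_mode = cfg$cost_mode %||% "linear",
    interactions = inter %||% DEFAULT_INTERACTIONS,
    optout_covariates = unlist(cfg$optout_covariates) %||% DEFAULT_OPTOUT_COVARIATES,
    optout_random = cfg$optout_random %||% FALSE,
    n_classes = cfg$n_classes %||% 1L,
    class_covariates = unlist(cfg$class_covariates) %||% DEFAULT_CLASS_COVARIATES
  )
}

# Names of the encoded vaccine-attribute columns implied by a spec.
attribute_column_names <- function(spec) {
  c(if (spec$cost_mode == "linear_plus_free") "free",
    "cost", "effectiveness", "protection", "incubation", "severe", "mild",
    "introduced",
    paste0("origin_", ORIGIN_DUMMIES),
    paste0("rec_", RECOMMENDER_DUMMIES))
}

interaction_column_names <- function(spec) {
  vapply(spec$interactions, function(p) paste0(p[1], "_x_", p[2]), "")
}
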