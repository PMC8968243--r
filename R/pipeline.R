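# End-to-end pipeline driver: simulate (or read) -> fit -> post-estimation ->
# model selection, with seeded, hash-stamped artifacts on disk.

# Polynomial rolling hash of the serialized config; stamps every artifact so
# a rerun with an edited config is distinguishable.
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full choice-modelling pipeline
#'
#' Executes simulate (or read) -> fit the requested model variants ->
#' post-estimation (WTP and odds-ratio tables; posterior class assignment for
#' latent-class fits; an optional cost scenario curve) -> a BIC model-selection
#' report. Every artifact is written under \code{out_dir} and stamped with the
#' run seed and a hash of the configuration; a structured log records
#' convergence diagnostics. Any stage failure halts with the stage named;
#' artifacts of completed stages are retained.
#'
#' @param config a list, or a path to a YAML/JSON file, with entries:
#'   \describe{
#'     \item{out_dir}{output directory (created if needed).}
#'     \item{seed}{integer master seed (default 1); all randomness derives
#'       from it.}
#'     \item{models}{character vector among \code{"cl1"}, \code{"cl2"},
#'       \code{"rpl1"}, \code{"rpl2"}, \code{"lcl2"}, \code{"lcl3"}
#'       (default \code{"cl1"}).}
#'     \item{input_csv}{optional path to an existing long-format choice CSV;
#'       when absent a dataset is simulated.}
#'     \item{simulate}{list: \code{n_respondents} (default 500),
#'       \code{truth_model} (default \code{"cl1"}), \code{n_scenarios},
#'       \code{tasks_per_respondent}.}
#'     \item{draws}{Halton draws per respondent for RPL fits (default 500).}
#'     \item{lcl}{list: \code{n_starts} (default 5), \code{maxit}.}
#'     \item{scenario}{optional list: \code{model} (fitted variant to use),
#'       \code{grid} (default 200-point cost grid 0..700).}
#'   }
#' @return Invisibly, a list with the fits, the selection table and the paths
#'   of all artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), sprintf(...), "\n",
        file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  artifacts <- character(0)
  emit <- function(path) {
    artifacts <<- c(artifacts, path)
    path
  }
  jsonlite::write_json(list(seed = seed, config_hash = hash, config = config),
                       emit(file.path(out_dir, "run_meta.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  data <- stage("data", {
    if (!is.null(config$input_csv)) {
      logf("reading %s", config$input_csv)
      read_choice_data(config$input_csv)
    } else {
      sim <- config$simulate %||% list()
      truth_model <- sim$truth_model %||% "cl1"
      dcfg <- design_config(n_scenarios = sim$n_scenarios %||% 24L,
                            tasks_per_respondent = sim$tasks_per_respondent %||% 7L,
                            seed = seed)
      pcfg <- population_config(n_respondents = sim$n_respondents %||% 500L,
                                seed = seed + 1L)
      spec_t <- spec_variant(truth_model)
      if (grepl("^lcl", truth_model)) {
        tp <- reference_lcl_parameters()
        d <- simulate_choices(generate_design(dcfg), sample_population(pcfg),
                              tp, "LCL", spec_t, seed = seed + 2L,
                              tasks_per_respondent = dcfg$tasks_per_respondent)
      } else {
        tp <- reference_parameters(truth_model)
        kind <- if (spec_t$optout_random) "RPL" else "CL"
        d <- simulate_choices(generate_design(dcfg), sample_population(pcfg),
                              tp, kind, spec_t, seed = seed + 2L,
                              tasks_per_respondent = dcfg$tasks_per_respondent)
      }
      logf("simulated %d tasks from truth model %s", nrow(d$tasks), truth_model)
      write_choice_data(d, emit(file.path(out_dir, "choices.csv")))
      d
    }
  })

  models <- config$models %||% "cl1"
  fits <- list()
  for (mname in models) {
    fits[[mname]] <- stage(paste0("fit_", mname), {
      spec <- spec_variant(mname)
      fit <- if (grepl("^lcl", mname)) {
        em_fit_lcl(data, spec, n_starts = config$lcl$n_starts %||% 5L,
                   seed = seed,
                   options = list(maxit = config$lcl$maxit %||% 2000L))
      } else if (spec$optout_random) {
        fit_rpl(data, spec, options = list(R = config$draws %||% 500L,
                                           seed = seed))
      } else {
        fit_conditional_logit(data, spec)
      }
      logf("%s: loglik %.3f BIC %.3f converged %s (%s iterations)",
           mname, fit$loglik, fit$bic, fit$converged,
           format(fit$iterations))
      write_fit_report(fit, emit(file.path(out_dir, paste0("fit_", mname, ".json"))))
      fit
    })
  }

  stage("postestimation", {
    for (mname in names(fits)) {
      fit <- fits[[mname]]
      if (inherits(fit, "lcl_fit")) {
        asg <- assign_classes(fit, data, seed = seed)
        write_table(class_assignment_odds(fit),
                    emit(file.path(out_dir, paste0("class_odds_", mname, ".csv"))))
        jsonlite::write_json(
          list(seed = seed, config_hash = hash,
               expected_shares = asg$expected_shares,
               realized_shares = asg$realized_shares,
               labels = unname(asg$labels)),
          emit(file.path(out_dir, paste0("classes_", mname, ".json"))),
          auto_unbox = TRUE, digits = NA)
      } else {
        write_table(wtp_table(fit),
                    emit(file.path(out_dir, paste0("wtp_", mname, ".csv"))))
        write_table(odds_ratios(fit),
                    emit(file.path(out_dir, paste0("or_", mname, ".csv"))))
      }
    }
  })

  if (!is.null(config$scenario)) {
    stage("scenario", {
      sc <- config$scenario
      mname <- sc$model %||% names(fits)[[1L]]
      fit <- fits[[mname]]
      if (inherits(fit, "lcl_fit")) stop("scenario curves need a CL/RPL fit")
      base_b <- vaccine_profile(cost = 0, effectiveness = 95, incubation = 21,
                                protection = 12, mild = 4, severe = 10,
                                recommender = "PCP", origin = "Germany",
                                introduced = 6)
      grid <- sc$grid %||% seq(0, 700, length.out = 200L)
      curve <- scenario_curves(fit, base_b, base_b,
                               representative_respondent(),
                               sc$varied_attribute %||% "cost", grid,
                               integration = list(method = sc$method %||% "mc",
                                                  seed = seed))
      utils::write.csv(curve$curve,
                       emit(file.path(out_dir, paste0("scenario_", mname, ".csv"))),
                       row.names = FALSE)
      logf("scenario over %s: %d crossings", curve$varied_attribute,
           length(curve$crossings))
    })
  }

  selection <- stage("selection", {
    tab <- model_selection(fits)
    tab$seed <- seed
    tab$config_hash <- hash
    utils::write.csv(tab, emit(file.path(out_dir, "selection.csv")),
                     row.names = FALSE)
    logf("selected: %s", tab$model[tab$selected])
    tab
  })

  invisible(list(fits = fits, selection = selection, data = data,
                 artifacts = artifacts, seed = seed, config_hash = hash))
}
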