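ATTRIBUTE_FIELDS <- c("cost", "effectiveness", "incubation", "protection",
                      "mild", "severe", "recommender", "origin", "introduced")

#' Assemble a choice dataset
#'
#' The internal container for a stated-choice panel: one row per task in
#' \code{tasks} (with alternative A and B attributes in \code{a_*} / \code{b_*}
#' columns and the observed choice among A, B and opt-out), and one row per
#' respondent in \code{respondents}.
#'
#' @param tasks data.frame with columns \code{resp_id}, \code{task_index},
#'   \code{chosen} (one of \code{"A"}, \code{"B"}, \code{"optout"}) and the
#'   prefixed attribute columns.
#' @param respondents data.frame with \code{resp_id} plus the respondent
#'   covariates.
#' @return Object of class \code{dce_data}.
#' @export
dce_data <- function(tasks, respondents) {
  need <- c("resp_id", "task_index", "chosen",
            paste0("a_", ATTRIBUTE_FIELDS), paste0("b_", ATTRIBUTE_FIELDS))
  miss <- setdiff(need, names(tasks))
  if (length(miss)) stop("tasks missing column(s): ", paste(miss, collapse = ", "))
  if (!all(tasks$chosen %in% c("A", "B", "optout"))) {
    stop("chosen must be one of 'A', 'B', 'optout'")
  }
  if (anyDuplicated(tasks[c("resp_id", "task_index")])) {
    stop("task_index must be unique within respondent")
  }
  if (anyDuplicated(respondents$resp_id)) stop("duplicate resp_id in respondents")
  if (!all(tasks$resp_id %in% respondents$resp_id)) {
    stop("tasks reference unknown respondents")
  }
  if (nrow(tasks) == 0L) stop("empty dataset")
  structure(list(tasks = tasks, respondents = respondents), class = "dce_data")
}

#' @export
print.dce_data <- function(x, ...) {
  cat("Stated-choice dataset:", nrow(x$tasks), "tasks from",
      nrow(x$respondents), "respondents\n")
  tab <- table(x$tasks$chosen)
  cat("  choice shares:",
      paste(sprintf("%s %.3f", names(tab), tab / sum(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a choice dataset as long-format CSV
#'
#' Emits the interchange format: one row per respondent x task x alternative
#' with columns \code{resp_id}, \code{task}, \code{alt} (A/B/optout),
#' \code{chosen} (0/1), the nine vaccine attribute columns (empty on opt-out
#' rows) and one column per respondent covariate.
#'
#' @param data a \code{\link{dce_data}}.
#' @param path output path.
#' @export
write_choice_data <- function(data, path) {
  tasks <- data$tasks
  n <- nrow(tasks)
  mk_side <- function(alt, prefix) {
    d <- data.frame(resp_id = tasks$resp_id, task = tasks$task_index,
                    alt = alt, chosen = as.integer(tasks$chosen == alt))
    for (a in ATTRIBUTE_FIELDS) d[[a]] <- tasks[[paste0(prefix, "_", a)]]
    d
  }
  opt <- data.frame(resp_id = tasks$resp_id, task = tasks$task_index,
                    alt = "optout", chosen = as.integer(tasks$chosen == "optout"))
  for (a in ATTRIBUTE_FIELDS) opt[[a]] <- NA
  long <- rbind(mk_side("A", "a"), mk_side("B", "b"), opt)
  cov_cols <- intersect(RESPONDENT_FIELDS, names(data$respondents))
  long <- cbind(long, data$respondents[match(long$resp_id,
                                             data$respondents$resp_id),
                                       cov_cols, drop = FALSE])
  long <- long[order(long$resp_id, long$task, match(long$alt, c("A", "B", "optout"))), ]
  rownames(long) <- NULL
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a long-format choice CSV into a validated dataset
#'
#' Rows are grouped into tasks of exactly three alternatives (A, B, opt-out)
#' with exactly one chosen row per task; violations are rejected with the
#' offending rows named.
#'
#' @param path path to a CSV written in the layout of
#'   \code{\link{write_choice_data}}.
#' @return A \code{\link{dce_data}}.
#' @export
read_choice_data <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("resp_id", "task", "alt", "chosen", ATTRIBUTE_FIELDS)
  miss <- setdiff(need, names(long))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(long$resp_id, long$task, long$alt)
  if (anyDuplicated(key)) {
    stop("duplicate (resp_id, task, alt) rows: ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "))
  }
  grp <- interaction(long$resp_id, long$task, drop = TRUE)
  sizes <- table(grp)
  if (any(sizes != 3L)) {
    stop("tasks without exactly 3 alternatives: ",
         paste(utils::head(names(sizes)[sizes != 3L], 5L), collapse = ", "))
  }
  chosen_per_task <- tapply(long$chosen, grp, sum)
  if (any(chosen_per_task != 1L)) {
    stop("tasks with zero or multiple chosen rows: ",
         paste(utils::head(names(chosen_per_task)[chosen_per_task != 1L], 5L),
               collapse = ", "))
  }
  a <- long[long$alt == "A", ]
  b <- long[long$alt == "B", ]
  o <- long[long$alt == "optout", ]
  a <- a[order(a$resp_id, a$task), ]
  b <- b[order(b$resp_id, b$task), ]
  o <- o[order(o$resp_id, o$task), ]
  chosen <- ifelse(a$chosen == 1, "A", ifelse(b$chosen == 1, "B", "optout"))
  tasks <- data.frame(resp_id = a$resp_id, task_index = a$task, chosen = chosen)
  for (f in ATTRIBUTE_FIELDS) tasks[[paste0("a_", f)]] <- a[[f]]
  for (f in ATTRIBUTE_FIELDS) tasks[[paste0("b_", f)]] <- b[[f]]
  cov_cols <- intersect(RESPONDENT_FIELDS, names(long))
  resp <- long[!duplicated(long$resp_id), c("resp_id", cov_cols)]
  resp <- resp[order(resp$resp_id), ]
  rownames(resp) <- rownames(tasks) <- NULL
  dce_data(tasks, resp)
}
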