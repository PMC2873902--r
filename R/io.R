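## Tab-delimited table I/O with schema checks. All pipeline tables are plain
## text with a header so that every stage can be run independently from
## files on disk.

check_schema <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s '%s' is missing column(s): %s",
                 what, path, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read / write fixation-level trial tables
#'
#' Trial tables are tab-delimited text with the columns `participant`,
#' `stimulus`, `fix_index`, `x_deg`, `y_deg`, `response` (fixation index 0
#' marks the excluded first fixation). Writing then reading a table
#' reproduces it exactly up to numeric formatting.
#'
#' @param path File path.
#' @param trials Data frame to write.
#' @return `read_trials` returns the data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_schema(df, c("participant", "stimulus", "fix_index",
                     "x_deg", "y_deg", "response"), "trial table", path)
  bad <- which(!is.finite(df$x_deg) | !is.finite(df$y_deg))
  if (length(bad)) {
    stop(sprintf("trial table '%s': malformed coordinate in line %d",
                 path, bad[1] + 1L))
  }
  df
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  check_schema(trials, c("participant", "stimulus", "fix_index",
                         "x_deg", "y_deg", "response"), "trial table", path)
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write per-bubble salience tables
#'
#' Two-column tab-delimited text (`bubble_id`, `salience`); the measure
#' name is kept in a comment-free header attribute column named by the
#' measure on write and restored on read via the `measure` argument.
#'
#' @param path File path.
#' @param salience A `salience_table`.
#' @param measure Measure label to attach on read.
#' @return `read_salience` returns a `salience_table`.
#' @export
read_salience <- function(path, measure = "empirical") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_schema(df, c("bubble_id", "salience"), "salience table", path)
  salience_table(stats::setNames(df$salience, df$bubble_id), measure)
}

#' @rdname read_salience
#' @export
write_salience <- function(salience, path) {
  check_schema(salience, c("bubble_id", "salience"), "salience table", path)
  utils::write.table(as.data.frame(salience)[, c("bubble_id", "salience")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write response tables
#'
#' Tab-delimited (`participant`, `stimulus`, `response`), one classification
#' response per trial.
#'
#' @param path File path.
#' @param responses Data frame to write.
#' @return `read_responses` returns the data frame.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_schema(df, c("participant", "stimulus", "response"),
               "response table", path)
  df
}

#' @rdname read_responses
#' @export
write_responses <- function(responses, path) {
  check_schema(responses, c("participant", "stimulus", "response"),
               "response table", path)
  utils::write.table(responses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the per-task correlation results as CSV
#'
#' One row per task and predictor with the pairwise correlation, the
#' semi-partial correlation, significance stars, and the task's R-squared
#' and F-test p-value.
#'
#' @param analyses Named list of [attention_analysis()] results (per task).
#' @param path Output CSV path.
#' @return The assembled data frame, invisibly.
#' @export
write_results_table <- function(analyses, path) {
  stars <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
  rows <- lapply(names(analyses), function(task) {
    a <- analyses[[task]]
    cbind(task = task, a$table,
          stars_r = stars(a$table$p_r), stars_sr = stars(a$table$p_sr),
          r_squared = a$r_squared, f_p = a$f_p)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
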