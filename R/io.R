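#' Read per-attempt outcome records
#'
#' Reads a comma-separated, UTF-8 file with a header row and columns
#' `trainee_id`, `group`, `attempt_no`, `score` (0 = success, 1 = failure),
#' and validates it: scores must be binary, at most two group labels may
#' appear, each trainee must carry a single group label, and each trainee's
#' attempt numbers must run 1..N with no gaps or duplicates. Violations are
#' rejected with row-numbered diagnostics (rows count data rows, header
#' excluded).
#'
#' @param path Path to the CSV file.
#' @return A validated data frame of attempt records.
#' @export
read_attempts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, encoding = "UTF-8")
  validate_attempts(df, where = path)
}

#' Validate a table of attempt records
#'
#' @param records Data frame with columns `trainee_id`, `group`,
#'   `attempt_no`, `score`.
#' @param where Label used in error messages (e.g. a file name).
#' @return The validated records, with `attempt_no` and `score` as integers.
#' @export
validate_attempts <- function(records, where = "records") {
  req <- c("trainee_id", "group", "attempt_no", "score")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop(where, ": missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0L)
    stop(where, ": no records", call. = FALSE)

  score_num <- suppressWarnings(as.numeric(records$score))
  bad <- which(is.na(score_num) | !(score_num %in% c(0, 1)))
  if (length(bad))
    stop(where, ": non-binary score on row ", bad[1],
         " (score = ", records$score[bad[1]], "); scores must be 0 or 1",
         call. = FALSE)
  att_num <- suppressWarnings(as.numeric(records$attempt_no))
  bad <- which(is.na(att_num) | att_num < 1 | att_num != floor(att_num))
  if (length(bad))
    stop(where, ": invalid attempt_no on row ", bad[1], call. = FALSE)

  groups <- unique(records$group)
  if (length(groups) > 2L)
    stop(where, ": more than two group labels found: ",
         paste(groups, collapse = ", "), call. = FALSE)

  records$score <- as.integer(score_num)
  records$attempt_no <- as.integer(att_num)
  records$trainee_id <- as.character(records$trainee_id)
  records$group <- as.character(records$group)

  # per-trainee contiguity and single group label, with row diagnostics
  idx <- split(seq_len(nrow(records)), records$trainee_id)
  for (id in names(idx)) {
    rows <- idx[[id]]
    g <- unique(records$group[rows])
    if (length(g) != 1L)
      stop(where, ": trainee ", id, " carries multiple group labels (",
           paste(g, collapse = ", "), "), first at row ", rows[1], call. = FALSE)
    att <- sort(records$attempt_no[rows])
    if (any(att != seq_along(att))) {
      off <- which(att != seq_along(att))[1]
      stop(where, ": trainee ", id, " has an attempt_no gap or duplicate ",
           "(position ", off, ": found ", att[off], ", expected ", off, "), ",
           "rows ", paste(range(rows), collapse = "-"), call. = FALSE)
    }
  }
  records
}

#' Write attempt records as CSV
#'
#' @param records Attempt-record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attempts <- function(records, path) {
  utils::write.csv(records[, c("trainee_id", "group", "attempt_no", "score")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full learning-curve analysis
#'
#' End-to-end pipeline: validate the records, classify every trainee at the
#' primary failure-rate setting, compare the cohorts, and re-run the
#' comparison across the sensitivity settings. The result is reproducible
#' bit-for-bit from the same inputs (no randomness is involved).
#'
#' @param records Attempt records (a data frame, or a path to a CSV read
#'   via [read_attempts()]).
#' @param rates Primary [failure_rates()] setting. Default (0.10, 0.30,
#'   0.10, 0.10).
#' @param sensitivity_settings Data frame with columns `p0`, `p1`; default
#'   the five settings 10/30, 10/40, 20/30, 20/35, 20/40 (percent scale
#'   divided by 100).
#' @param chart_tables If `TRUE`, include a per-trainee [chart_table()]
#'   list in the result.
#' @return An object of class `"cusum_analysis"`: a list with `constants`,
#'   `classification`, `comparison`, `sensitivity` (summary data frame),
#'   `sensitivity_detail`, and optionally `charts`.
#' @export
run_analysis <- function(records,
                         rates = failure_rates(0.10, 0.30, 0.10, 0.10),
                         sensitivity_settings = default_sensitivity_settings(),
                         chart_tables = FALSE) {
  if (is.character(records) && length(records) == 1L)
    records <- read_attempts(records)
  else
    records <- validate_attempts(records)

  constants <- sprt_constants(rates)
  comparison <- compare_cohorts(records, rates)
  grid <- sensitivity_grid(records, sensitivity_settings,
                           alpha = rates$alpha, beta = rates$beta)
  charts <- NULL
  if (chart_tables) {
    charts <- lapply(split(records, records$trainee_id), function(rec)
      chart_table(build_series(rec), constants))
  }
  structure(list(
    rates = rates, constants = constants,
    classification = comparison$classification,
    comparison = comparison,
    sensitivity = attr(grid, "summary"),
    sensitivity_detail = grid,
    charts = charts
  ), class = "cusum_analysis")
}

#' Default sensitivity settings for the failure-rate grid
#'
#' The five (p0, p1) pairs 0.10/0.30, 0.10/0.40, 0.20/0.30, 0.20/0.35,
#' 0.20/0.40 commonly examined when stress-testing the choice of acceptable
#' and unacceptable failure rates.
#'
#' @return A data frame with columns `p0` and `p1`.
#' @export
default_sensitivity_settings <- function() {
  data.frame(p0 = c(0.10, 0.10, 0.20, 0.20, 0.20),
             p1 = c(0.30, 0.40, 0.30, 0.35, 0.40))
}

#' @export
print.cusum_analysis <- function(x, ...) {
  cat("CUSUM learning-curve analysis\n")
  cat("-----------------------------\n")
  print(x$comparison)
  cat("\nSensitivity to the failure-rate setting:\n")
  print(x$sensitivity, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write an analysis report to a directory
#'
#' Emits `report.json` (machine-readable), `report.txt` (aligned tables),
#' `classification.csv`, `sensitivity.csv` and, when the analysis carries
#' chart tables, one `chart_<trainee>.csv` per trainee.
#'
#' @param analysis A [run_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "cusum_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  utils::write.csv(analysis$classification,
                   file.path(dir, "classification.csv"), row.names = FALSE)
  utils::write.csv(analysis$sensitivity,
                   file.path(dir, "sensitivity.csv"), row.names = FALSE)

  txt <- c("CUSUM learning-curve analysis report", "",
           format(analysis$constants), "",
           utils::capture.output(print(analysis)))
  writeLines(txt, file.path(dir, "report.txt"))

  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cc <- analysis$comparison
    json <- list(
      rates = unclass(analysis$rates),
      constants = unclass(analysis$constants)[c("a", "b", "P", "Q", "s",
                                                "h0_intercept", "h1_intercept")],
      estimable = isTRUE(cc$estimable),
      classification = analysis$classification,
      sensitivity = analysis$sensitivity
    )
    if (isTRUE(cc$estimable)) {
      json$comparison <- list(
        table = as.list(as.data.frame(as.table(cc$table))),
        study_pct = cc$study_pct, control_pct = cc$control_pct,
        or = cc$or[c("or", "ci_low", "ci_high", "pvalue", "continuity")],
        logistic = cc$logistic[c("or", "ci_low", "ci_high", "pvalue",
                                 "converged", "separation")],
        attempts_study = cc$attempts_study,
        attempts_control = cc$attempts_control,
        attempts_test = cc$attempts_test
      )
    }
    jsonlite::write_json(json, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(analysis$charts)) {
    for (id in names(analysis$charts)) {
      utils::write.csv(analysis$charts[[id]],
                       file.path(dir, paste0("chart_", id, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}
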