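#' Build a trainee's cumulative-failure series
#'
#' Orders one trainee's attempt records by attempt number, validates that
#' the attempt numbers run 1..N without gaps or duplicates and that every
#' score is binary (0 = success, 1 = failure), and computes the running
#' failure total charted on the CUSUM plot.
#'
#' @param records A data frame of attempt records for a single trainee, with
#'   columns `trainee_id`, `group`, `attempt_no`, `score`.
#' @return An object of class `"trainee_series"`: a list with `trainee_id`,
#'   `group`, `scores` (ordered 0/1 vector) and `cumsum` (running failure
#'   count, same length).
#' @examples
#' rec <- data.frame(trainee_id = "t1", group = "study",
#'                   attempt_no = 1:4, score = c(0, 0, 1, 0))
#' build_series(rec)$cumsum   # 0 0 1 1
#' @export
build_series <- function(records) {
  req <- c("trainee_id", "group", "attempt_no", "score")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop("records must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L)
    stop("empty record set: a trainee series needs at least one attempt", call. = FALSE)
  ids <- unique(records$trainee_id)
  if (length(ids) != 1L)
    stop("records span more than one trainee_id: ",
         paste(ids, collapse = ", "), call. = FALSE)
  grp <- unique(records$group)
  if (length(grp) != 1L)
    stop("inconsistent group label for trainee ", ids, call. = FALSE)

  ord <- order(records$attempt_no)
  att <- records$attempt_no[ord]
  sc  <- records$score[ord]

  bad_score <- which(!(sc %in% c(0, 1)))
  if (length(bad_score))
    stop("non-binary score for trainee ", ids, " at attempt_no ",
         att[bad_score[1]], " (score = ", sc[bad_score[1]], ")", call. = FALSE)
  expected <- seq_len(length(att))
  if (!isTRUE(all.equal(as.numeric(att), as.numeric(expected)))) {
    off <- which(att != expected)[1]
    stop("attempt_no sequence for trainee ", ids,
         " must be 1..N with no gaps or duplicates; first offending index ",
         off, " (found attempt_no ", att[off], ", expected ", expected[off], ")",
         call. = FALSE)
  }

  structure(
    list(trainee_id = ids, group = grp,
         scores = as.integer(sc), cumsum = cumsum(as.integer(sc))),
    class = "trainee_series"
  )
}

#' @export
print.trainee_series <- function(x, ...) {
  n <- length(x$scores)
  cat(sprintf("trainee series '%s' (group %s): %d attempts, %d failures\n",
              x$trainee_id, x$group, n, x$cumsum[n]))
  invisible(x)
}

#' Classify competence by first boundary crossing
#'
#' Scans the trainee's cumulative-failure chart in attempt order and returns
#' the first-crossing verdict: `competent` the first time the cumulative
#' failure count falls on or below the lower control line `h0(n)`,
#' `unacceptable` the first time it lies on or above the upper line `h1(n)`,
#' and `indeterminate` if neither happens within the observed attempts.
#' Touching a line counts as a crossing, and at any given attempt the lower
#' line is tested before the upper one, so exact simultaneous contact
#' resolves in the trainee's favour. The first crossing is terminal: later
#' recrossings are ignored.
#'
#' @param series A [build_series()] object.
#' @param constants An [sprt_constants()] object.
#' @return An object of class `"competence_result"`: a list with
#'   `trainee_id`, `group`, `status` (one of `"competent"`,
#'   `"unacceptable"`, `"indeterminate"`), `crossing_attempt`
#'   (integer, `NA` when indeterminate) and `n_attempts`.
#' @examples
#' k <- sprt_constants(failure_rates(0.10, 0.30))
#' s <- build_series(data.frame(trainee_id = "t", group = "study",
#'                              attempt_no = 1:12, score = 0))
#' classify_competence(s, k)   # competent at attempt 9
#' @export
classify_competence <- function(series, constants) {
  stopifnot(inherits(series, "trainee_series"),
            inherits(constants, "sprt_constants"))
  n  <- seq_along(series$scores)
  cs <- series$cumsum
  h0 <- constants$s * n - constants$h0_intercept
  h1 <- constants$s * n + constants$h1_intercept
  lo <- which(cs <= h0)
  hi <- which(cs >= h1)
  first_lo <- if (length(lo)) lo[1L] else Inf
  first_hi <- if (length(hi)) hi[1L] else Inf

  if (is.finite(first_lo) && first_lo <= first_hi) {
    status <- "competent"; cross <- as.integer(first_lo)
  } else if (is.finite(first_hi)) {
    status <- "unacceptable"; cross <- as.integer(first_hi)
  } else {
    status <- "indeterminate"; cross <- NA_integer_
  }
  structure(
    list(trainee_id = series$trainee_id, group = series$group,
         status = status, crossing_attempt = cross,
         n_attempts = length(n)),
    class = "competence_result"
  )
}

#' @export
print.competence_result <- function(x, ...) {
  cat(sprintf("trainee '%s' (%s): %s%s over %d attempts\n",
              x$trainee_id, x$group, x$status,
              if (!is.na(x$crossing_attempt))
                sprintf(" at attempt %d", x$crossing_attempt) else "",
              x$n_attempts))
  invisible(x)
}

#' Classify every trainee in a cohort
#'
#' Convenience wrapper: splits a full attempt-record table by trainee,
#' builds each series and classifies it against the given boundaries.
#'
#' @param records Attempt records for one or more trainees (see
#'   [read_attempts()] for the schema).
#' @param constants An [sprt_constants()] object.
#' @return A data frame, one row per trainee: `trainee_id`, `group`,
#'   `n_attempts`, `total_failures`, `status`, `crossing_attempt`.
#' @export
classify_cohort <- function(records, constants) {
  parts <- split(records, records$trainee_id)
  rows <- lapply(parts, function(rec) {
    s <- build_series(rec)
    r <- classify_competence(s, constants)
    data.frame(trainee_id = r$trainee_id, group = r$group,
               n_attempts = r$n_attempts,
               total_failures = s$cumsum[length(s$cumsum)],
               status = r$status, crossing_attempt = r$crossing_attempt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise attempts needed to reach competence
#'
#' Mean and sample standard deviation of the competence crossing attempt,
#' over competent trainees only. Indeterminate and unacceptable trainees are
#' excluded. With a single competent trainee the standard deviation is
#' reported as 0 and flagged via `degenerate = TRUE`; with none, an empty
#' summary is returned rather than an error.
#'
#' @param results A list of [classify_competence()] results, or a
#'   classification data frame from [classify_cohort()].
#' @return A list with `mean`, `sd`, `n` and logical `degenerate`.
#' @examples
#' attempts_to_competence(data.frame(status = c("competent", "competent"),
#'                                   crossing_attempt = c(10, 20)))
#' @export
attempts_to_competence <- function(results) {
  if (is.data.frame(results)) {
    status <- results$status
    cross  <- results$crossing_attempt
  } else {
    status <- vapply(results, `[[`, character(1), "status")
    cross  <- vapply(results, function(r)
      as.numeric(r$crossing_attempt %||% NA_real_), numeric(1))
  }
  x <- cross[status == "competent"]
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L)
    return(list(mean = NA_real_, sd = NA_real_, n = 0L, degenerate = TRUE))
  list(mean = mean(x),
       sd = if (n == 1L) 0 else stats::sd(x),
       n = n,
       degenerate = n == 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chart table for one trainee
#'
#' Per-attempt table of the cumulative failure count and both control
#' lines, suitable for plotting or export as delimited text.
#'
#' @param series A [build_series()] object.
#' @param constants An [sprt_constants()] object.
#' @return Data frame with columns `n`, `cum_failures`, `h0`, `h1`.
#' @export
chart_table <- function(series, constants) {
  stopifnot(inherits(series, "trainee_series"))
  b <- boundary_values(constants, seq_along(series$scores))
  data.frame(n = b$n, cum_failures = series$cumsum, h0 = b$h0, h1 = b$h1)
}

#' Plot a trainee's CUSUM chart
#'
#' Cumulative failures against attempt number as a step curve, with the
#' acceptable (lower) and unacceptable (upper) control lines.
#'
#' @param x A [build_series()] object.
#' @param constants An [sprt_constants()] object.
#' @param ... Further arguments passed to [plot()].
#' @return Invisibly, the [chart_table()] that was drawn.
#' @export
plot.trainee_series <- function(x, constants, ...) {
  tab <- chart_table(x, constants)
  ylim <- range(0, tab$cum_failures, tab$h1, pmax(tab$h0, 0))
  plot(tab$n, tab$cum_failures, type = "s", lwd = 2,
       xlab = "attempt number", ylab = "cumulative failures",
       ylim = ylim,
       main = sprintf("CUSUM chart: trainee %s (%s)", x$trainee_id, x$group),
       ...)
  lines(tab$n, tab$h0, lty = 2, col = "forestgreen")
  lines(tab$n, tab$h1, lty = 2, col = "firebrick")
  legend("topleft", bty = "n", lty = c(1, 2, 2), lwd = c(2, 1, 1),
         col = c("black", "forestgreen", "firebrick"),
         legend = c("cumulative failures", "h0 (acceptable)", "h1 (unacceptable)"))
  invisible(tab)
}
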