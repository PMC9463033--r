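#' Odds ratio for a 2x2 achievement table
#'
#' Cross-product odds ratio with a Woolf (log-OR) 95% confidence interval
#' and a two-sided p-value from the log-OR z statistic. When any cell is
#' zero the Haldane-Anscombe correction (0.5 added to every cell) is applied
#' and flagged; when an entire row or column is zero the odds ratio is
#' undefined and reported as `NA`.
#'
#' @param study_yes,study_no Achievers / non-achievers in the study group.
#' @param control_yes,control_no Achievers / non-achievers in the control group.
#' @param conf_level Confidence level for the Woolf interval. Default 0.95.
#' @return A list with `or`, `ci_low`, `ci_high`, `pvalue`,
#'   `continuity` (TRUE when the 0.5 correction was applied) and
#'   `table` (the 2x2 counts as entered).
#' @examples
#' odds_ratio_2x2(14, 7, 8, 13)$or   # 3.25
#' @export
odds_ratio_2x2 <- function(study_yes, study_no, control_yes, control_no,
                           conf_level = 0.95) {
  cells <- c(study_yes = study_yes, study_no = study_no,
             control_yes = control_yes, control_no = control_no)
  if (any(!is.finite(cells)) || any(cells < 0))
    stop("all 2x2 cell counts must be finite and non-negative", call. = FALSE)
  tab <- matrix(cells, nrow = 2, byrow = TRUE,
                dimnames = list(c("study", "control"), c("yes", "no")))
  out <- list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              pvalue = NA_real_, continuity = FALSE, table = tab)

  # zero margin (whole row or column empty): OR undefined
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    out$note <- "zero margin: odds ratio undefined"
    return(out)
  }
  a <- study_yes; b <- study_no; c <- control_yes; d <- control_no
  if (any(cells == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    out$continuity <- TRUE
  }
  lor <- log(a) + log(d) - log(b) - log(c)
  se  <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z   <- stats::qnorm(1 - (1 - conf_level) / 2)
  out$or      <- (a * d) / (b * c)
  out$ci_low  <- exp(lor - z * se)
  out$ci_high <- exp(lor + z * se)
  out$pvalue  <- 2 * stats::pnorm(-abs(lor / se))
  out
}

#' Logistic regression of achievement on group, fitted by IRLS
#'
#' Maximum-likelihood logistic regression of a binary achievement indicator
#' on a single binary group indicator, fitted by iteratively reweighted
#' least squares implemented here. For this saturated two-group model the
#' exponentiated group coefficient equals the crude odds ratio of the
#' corresponding 2x2 table, which serves as a cross-check. Complete or
#' quasi-complete separation (a zero cell in the 2x2 table, so the MLE is
#' infinite) is detected and reported as non-convergence rather than a
#' silent estimate.
#'
#' @param achieved Binary (0/1 or logical) achievement per trainee.
#' @param group Group label per trainee; must take exactly two values.
#' @param study_label The label treated as the exposure (coded 1). Defaults
#'   to `"study"` when present, otherwise the second sorted label.
#' @param conf_level Confidence level for the Wald interval. Default 0.95.
#' @param maxit,tol IRLS iteration cap and convergence tolerance on the
#'   score norm.
#' @return A list with `or` (= exp(coefficient)), `ci_low`, `ci_high`,
#'   `pvalue`, `coef` (intercept and group log-odds), `converged`, and
#'   `separation` (TRUE when the MLE diverges).
#' @examples
#' ach <- c(rep(1, 14), rep(0, 7), rep(1, 8), rep(0, 13))
#' grp <- rep(c("study", "control"), each = 21)
#' logistic_or(ach, grp)$or   # 3.25
#' @export
logistic_or <- function(achieved, group, study_label = NULL,
                        conf_level = 0.95, maxit = 100L, tol = 1e-12) {
  y <- as.numeric(achieved)
  if (any(!(y %in% c(0, 1)))) stop("'achieved' must be binary 0/1", call. = FALSE)
  labs <- sort(unique(as.character(group)))
  if (length(labs) != 2L)
    stop("'group' must contain exactly two labels; found ",
         length(labs), call. = FALSE)
  if (is.null(study_label))
    study_label <- if ("study" %in% labs) "study" else labs[2]
  if (!study_label %in% labs)
    stop("study_label '", study_label, "' not present in group labels", call. = FALSE)
  x <- as.numeric(group == study_label)
  if (length(y) != length(x)) stop("length mismatch", call. = FALSE)

  X <- cbind(1, x)
  beta <- c(0, 0)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu  <- stats::plogis(eta)
    w   <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    info  <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- unname(beta + step)
    if (max(abs(score)) < tol || max(abs(step)) < 1e-10) { converged <- TRUE; break }
    if (max(abs(beta)) > 30) break   # diverging: separation
  }
  separation <- !converged || max(abs(beta)) > 30

  if (separation) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                pvalue = NA_real_, coef = beta, converged = FALSE,
                separation = TRUE,
                note = "complete or quasi-complete separation: group coefficient MLE is infinite"))
  }
  eta <- drop(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  vcov <- solve(crossprod(X * w, X))
  se <- sqrt(vcov[2, 2])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(beta[2]),
       ci_low = exp(beta[2] - z * se),
       ci_high = exp(beta[2] + z * se),
       pvalue = 2 * stats::pnorm(-abs(beta[2] / se)),
       coef = beta, converged = TRUE, separation = FALSE)
}

#' Welch two-sample t-test on attempts to competence
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. When both samples have zero variance the
#' statistic is degenerate: the test reports p = 1 if the means are equal
#' and p = 0 otherwise, with `degenerate = TRUE`.
#'
#' @param x,y Numeric samples, each of size at least 2.
#' @return A list with `t`, `df`, `pvalue`, and `degenerate`.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("welch_t requires at least 2 observations per sample (got ",
         length(x), " and ", length(y), ")", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                df = NA_real_, pvalue = if (eq) 1 else 0,
                degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       pvalue = ht$p.value, degenerate = FALSE)
}

#' Ratio of two proportions with Katz log-ratio confidence interval
#'
#' @param x_yes,x_n Successes and denominator in the first group.
#' @param y_yes,y_n Successes and denominator in the second group.
#' @param conf_level Confidence level. Default 0.95.
#' @return A list with `ratio`, `ci_low`, `ci_high`, and `continuity`
#'   (TRUE when a 0.5 correction to a zero numerator was used for the CI).
#'   When `y_yes` is 0 the ratio is undefined and reported as `NA`.
#' @examples
#' proportion_ratio(14, 21, 8, 21)$ratio   # 1.75
#' @export
proportion_ratio <- function(x_yes, x_n, y_yes, y_n, conf_level = 0.95) {
  if (x_n <= 0 || y_n <= 0) stop("denominators must be positive", call. = FALSE)
  if (x_yes < 0 || y_yes < 0 || x_yes > x_n || y_yes > y_n)
    stop("counts must satisfy 0 <= yes <= n", call. = FALSE)
  if (y_yes == 0)
    return(list(ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                continuity = FALSE, note = "reference proportion is zero: ratio undefined"))
  ratio <- (x_yes / x_n) / (y_yes / y_n)
  continuity <- x_yes == 0
  a <- if (continuity) x_yes + 0.5 else x_yes
  b <- y_yes
  lrr <- log((a / x_n) / (b / y_n))
  se  <- sqrt(1 / a - 1 / x_n + 1 / b - 1 / y_n)
  z   <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(ratio = ratio,
       ci_low = if (x_yes == 0) 0 else exp(lrr - z * se),
       ci_high = exp(lrr + z * se),
       continuity = continuity)
}

#' Integer percentage, rounding half away from zero
#'
#' Reporting convention for achievement tables: `100 * yes / n` rounded to
#' the nearest integer, halves away from zero (66.67 -> 67, 12.5 -> 13).
#'
#' @param yes Numerator count.
#' @param n Denominator count.
#' @return Integer percent.
#' @export
percent_int <- function(yes, n) {
  p <- 100 * yes / n
  as.integer(sign(p) * floor(abs(p) + 0.5))
}

#' Compare two cohorts on competence achievement
#'
#' Classifies every trainee against the boundaries implied by `rates`,
#' builds the 2x2 achievement table (indeterminate and unacceptable
#' trainees count as non-achievers), and computes the crude odds ratio with
#' Woolf CI, the IRLS logistic fit, attempts-to-competence summaries per
#' group and a Welch t-test comparing them.
#'
#' @param records Attempt records for both cohorts (see [read_attempts()]).
#' @param rates A [failure_rates()] object.
#' @param study_label,control_label Group labels; defaults `"study"` and
#'   `"control"`.
#' @return An object of class `"cohort_comparison"`: a list with the
#'   classification data frame, the 2x2 `table`, `study_pct`/`control_pct`
#'   (integer percent achievers), `or` (from [odds_ratio_2x2()]),
#'   `logistic` (from [logistic_or()]), `attempts_study`,
#'   `attempts_control` (from [attempts_to_competence()]),
#'   `attempts_test` (from [welch_t()], `NULL` when either group has fewer
#'   than 2 competent trainees), and `estimable` (FALSE with a `note` when
#'   one of the two groups is absent).
#' @export
compare_cohorts <- function(records, rates,
                            study_label = "study", control_label = "control") {
  constants <- sprt_constants(rates)
  cls <- classify_cohort(records, constants)

  present <- unique(cls$group)
  if (!(study_label %in% present) || !(control_label %in% present)) {
    return(structure(list(
      classification = cls, estimable = FALSE,
      note = sprintf("comparison not estimable: need both '%s' and '%s' groups, found: %s",
                     study_label, control_label, paste(present, collapse = ", ")),
      rates = rates), class = "cohort_comparison"))
  }

  is_study <- cls$group == study_label
  ach <- cls$status == "competent"
  sy <- sum(ach & is_study);  sn <- sum(!ach & is_study)
  cy <- sum(ach & !is_study); cn <- sum(!ach & !is_study)

  or <- odds_ratio_2x2(sy, sn, cy, cn)
  lg <- logistic_or(as.numeric(ach), ifelse(is_study, study_label, control_label),
                    study_label = study_label)
  as <- attempts_to_competence(cls[is_study, ])
  ac <- attempts_to_competence(cls[!is_study, ])
  wt <- if (as$n >= 2 && ac$n >= 2) {
    welch_t(cls$crossing_attempt[is_study & ach],
            cls$crossing_attempt[!is_study & ach])
  } else NULL

  structure(list(
    classification = cls,
    table = or$table,
    study_pct = percent_int(sy, sy + sn),
    control_pct = percent_int(cy, cy + cn),
    or = or, logistic = lg,
    attempts_study = as, attempts_control = ac,
    attempts_test = wt,
    estimable = TRUE, rates = rates
  ), class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("Cohort comparison at p0 = %g, p1 = %g (alpha = %g, beta = %g)\n",
              x$rates$p0, x$rates$p1, x$rates$alpha, x$rates$beta))
  if (!isTRUE(x$estimable)) {
    cat("  ", x$note, "\n", sep = "")
    return(invisible(x))
  }
  tab <- x$or$table
  cat(sprintf("  achievers: study %d/%d (%d%%), control %d/%d (%d%%)\n",
              tab["study", "yes"], sum(tab["study", ]), x$study_pct,
              tab["control", "yes"], sum(tab["control", ]), x$control_pct))
  cat(sprintf("  crude OR %.3g (95%% CI %.3g-%.3g), p = %.3g%s\n",
              x$or$or, x$or$ci_low, x$or$ci_high, x$or$pvalue,
              if (x$or$continuity) " [0.5 continuity correction]" else ""))
  if (isTRUE(x$logistic$separation)) {
    cat("  logistic fit: separation, no finite estimate\n")
  } else {
    cat(sprintf("  logistic OR %.3g, p = %.3g\n", x$logistic$or, x$logistic$pvalue))
  }
  f <- function(s) if (s$n) sprintf("%.1f (+/-%.1f, n=%d)", s$mean, s$sd, s$n) else "none"
  cat(sprintf("  attempts to competence: study %s, control %s\n",
              f(x$attempts_study), f(x$attempts_control)))
  if (!is.null(x$attempts_test))
    cat(sprintf("  Welch t = %.3g, df = %.3g, p = %.3g\n",
                x$attempts_test$t, x$attempts_test$df, x$attempts_test$pvalue))
  invisible(x)
}

#' Sensitivity of the cohort comparison to the failure-rate setting
#'
#' Re-runs the full comparison for each (p0, p1) setting: recomputes the
#' boundaries, reclassifies every trainee, rebuilds the 2x2 table and the
#' associated statistics. Rows are returned in the order of `settings`.
#'
#' @param records Attempt records for both cohorts.
#' @param settings A data frame (or list of pairs) with columns `p0`, `p1`.
#' @param alpha,beta Error rates shared across settings. Default 0.10.
#' @param ... Passed to [compare_cohorts()].
#' @return A list of class `"sensitivity_grid"`: one [compare_cohorts()]
#'   result per setting, with a `summary` data frame attribute (columns
#'   `p0`, `p1`, `study_yes`, `study_pct`, `control_yes`, `control_pct`,
#'   `or`, `or_ci_low`, `or_ci_high`, `or_pvalue`, `attempts_study_mean`,
#'   `attempts_study_sd`, `attempts_control_mean`, `attempts_control_sd`,
#'   `attempts_pvalue`).
#' @export
sensitivity_grid <- function(records, settings, alpha = 0.10, beta = 0.10, ...) {
  if (!is.data.frame(settings)) settings <- do.call(rbind.data.frame, settings)
  names(settings)[1:2] <- c("p0", "p1")
  if (nrow(settings) == 0L) stop("'settings' must be non-empty", call. = FALSE)
  if (any(settings$p0 >= settings$p1))
    stop("every setting must satisfy p0 < p1", call. = FALSE)

  comps <- lapply(seq_len(nrow(settings)), function(i) {
    compare_cohorts(records,
                    failure_rates(settings$p0[i], settings$p1[i], alpha, beta),
                    ...)
  })
  rows <- lapply(seq_along(comps), function(i) {
    cc <- comps[[i]]
    if (!isTRUE(cc$estimable)) {
      return(data.frame(
        p0 = settings$p0[i], p1 = settings$p1[i],
        study_yes = NA_integer_, study_pct = NA_integer_,
        control_yes = NA_integer_, control_pct = NA_integer_,
        or = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
        or_pvalue = NA_real_,
        attempts_study_mean = NA_real_, attempts_study_sd = NA_real_,
        attempts_control_mean = NA_real_, attempts_control_sd = NA_real_,
        attempts_pvalue = NA_real_))
    }
    data.frame(
      p0 = settings$p0[i], p1 = settings$p1[i],
      study_yes = cc$table["study", "yes"], study_pct = cc$study_pct,
      control_yes = cc$table["control", "yes"], control_pct = cc$control_pct,
      or = cc$or$or, or_ci_low = cc$or$ci_low, or_ci_high = cc$or$ci_high,
      or_pvalue = cc$or$pvalue,
      attempts_study_mean = cc$attempts_study$mean,
      attempts_study_sd = cc$attempts_study$sd,
      attempts_control_mean = cc$attempts_control$mean,
      attempts_control_sd = cc$attempts_control$sd,
      attempts_pvalue = if (is.null(cc$attempts_test)) NA_real_
                        else cc$attempts_test$pvalue
    )
  })
  structure(comps, summary = do.call(rbind, rows), class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, digits = 3, ...) {
  cat("Sensitivity of cohort comparison to failure-rate settings\n")
  print(attr(x, "summary"), digits = digits, row.names = FALSE)
  invisible(x)
}
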