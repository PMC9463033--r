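test_that("crude odds ratios reproduce the published 2x2 tables", {
  expect_equal(odds_ratio_2x2(14, 7, 8, 13)$or, 3.25, tolerance = 1e-12)
  expect_equal(odds_ratio_2x2(16, 5, 16, 5)$or, 1, tolerance = 1e-12)
  expect_equal(odds_ratio_2x2(9, 12, 7, 14)$or, 1.5, tolerance = 1e-12)
  expect_equal(odds_ratio_2x2(16, 5, 14, 7)$or, 1.6, tolerance = 1e-12)
})

test_that("Woolf interval brackets the odds ratio and matches the closed form", {
  r <- odds_ratio_2x2(14, 7, 8, 13)
  expect_lte(r$ci_low, r$or)
  expect_gte(r$ci_high, r$or)
  se <- sqrt(1 / 14 + 1 / 7 + 1 / 8 + 1 / 13)
  expect_equal(r$ci_low, exp(log(3.25) - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(r$ci_high, exp(log(3.25) + qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(r$pvalue, 2 * pnorm(-abs(log(3.25) / se)), tolerance = 1e-12)
})

test_that("zero cells trigger the continuity correction; zero margins are undefined", {
  r <- odds_ratio_2x2(10, 0, 5, 5)
  expect_true(r$continuity)
  expect_equal(r$or, (10.5 * 5.5) / (0.5 * 5.5), tolerance = 1e-12)

  r <- odds_ratio_2x2(0, 0, 5, 5)   # empty study row
  expect_true(is.na(r$or))
  expect_match(r$note, "zero margin")

  expect_error(odds_ratio_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("IRLS logistic fit equals the crude odds ratio and the glm oracle", {
  tables <- list(c(14, 7, 8, 13), c(16, 5, 16, 5), c(9, 12, 7, 14),
                 c(16, 5, 14, 7), c(13, 8, 7, 14))
  for (tb in tables) {
    ach <- c(rep(1, tb[1]), rep(0, tb[2]), rep(1, tb[3]), rep(0, tb[4]))
    grp <- c(rep("study", tb[1] + tb[2]), rep("control", tb[3] + tb[4]))
    fit <- logistic_or(ach, grp)
    crude <- odds_ratio_2x2(tb[1], tb[2], tb[3], tb[4])$or
    expect_equal(fit$or, crude, tolerance = 1e-6)

    ref <- glm(ach ~ I(grp == "study"), family = binomial())
    expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$pvalue,
                 summary(ref)$coefficients[2, 4], tolerance = 1e-6)
  }
})

test_that("logistic fit flags identical groups and separation", {
  ach <- c(rep(1, 10), rep(0, 11), rep(1, 10), rep(0, 11))
  grp <- rep(c("study", "control"), each = 21)
  expect_equal(logistic_or(ach, grp)$or, 1, tolerance = 1e-9)

  ach <- c(rep(1, 21), rep(1, 8), rep(0, 13))   # study all-yes: infinite MLE
  fit <- logistic_or(ach, grp)
  expect_true(fit$separation)
  expect_false(fit$converged)
  expect_true(is.na(fit$or))

  expect_error(logistic_or(c(0, 1), c("a", "a")), "two labels")
  expect_error(logistic_or(c(0, 1, 0), c("a", "b", "c")), "two labels")
})

test_that("Welch test matches the hand formula and the t.test oracle", {
  r <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.6742, tolerance = 1e-4)
  ref <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(r$pvalue, ref$p.value, tolerance = 1e-12)

  r <- welch_t(c(3, 8, 1, 9), c(3, 8, 1, 9))
  expect_equal(r$t, 0, tolerance = 1e-12)
  expect_equal(r$pvalue, 1, tolerance = 1e-12)

  r <- welch_t(c(5, 5, 5), c(5, 5))        # degenerate, equal means
  expect_true(r$degenerate)
  expect_equal(r$t, 0); expect_equal(r$pvalue, 1)
  r <- welch_t(c(5, 5), c(7, 7))           # degenerate, unequal means
  expect_equal(r$pvalue, 0)

  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("proportion ratio and its Katz interval behave at the edges", {
  expect_equal(proportion_ratio(10, 20, 10, 20)$ratio, 1, tolerance = 1e-12)
  r <- proportion_ratio(14, 21, 8, 21)
  expect_equal(r$ratio, 1.75, tolerance = 1e-12)
  expect_lte(r$ci_low, r$ratio); expect_gte(r$ci_high, r$ratio)

  r <- proportion_ratio(0, 20, 10, 20)
  expect_equal(r$ratio, 0)
  expect_true(r$continuity)
  expect_equal(r$ci_low, 0)

  r <- proportion_ratio(5, 20, 0, 20)
  expect_true(is.na(r$ratio))
  expect_error(proportion_ratio(1, 0, 1, 5), "positive")
})

test_that("integer percentages round half away from zero", {
  expect_equal(percent_int(14, 21), 67L)   # 66.67
  expect_equal(percent_int(8, 21), 38L)    # 38.10
  expect_equal(percent_int(16, 21), 76L)
  expect_equal(percent_int(13, 21), 62L)   # 61.90 rounds to 62
  expect_equal(percent_int(1, 8), 13L)     # 12.5 rounds away from zero
})

test_that("cohort comparison on the bundled cohort reproduces the engineered table", {
  rec <- read_attempts(fixture_path())
  cc <- compare_cohorts(rec, failure_rates(0.10, 0.30))
  expect_true(cc$estimable)
  expect_equal(unname(cc$table["study", "yes"]), 14)
  expect_equal(unname(cc$table["control", "yes"]), 8)
  expect_equal(cc$study_pct, 67L)
  expect_equal(cc$control_pct, 38L)
  expect_equal(cc$or$or, 3.25, tolerance = 1e-12)
  expect_equal(cc$logistic$or, 3.25, tolerance = 1e-6)
  expect_equal(cc$attempts_study$n, 14L)
  expect_equal(cc$attempts_control$n, 8L)
  expect_false(is.null(cc$attempts_test))
})

test_that("a single-setting grid equals the direct comparison path", {
  rec <- read_attempts(fixture_path())
  g <- sensitivity_grid(rec, data.frame(p0 = 0.10, p1 = 0.30))
  direct <- compare_cohorts(rec, failure_rates(0.10, 0.30))
  row <- attr(g, "summary")
  expect_equal(nrow(row), 1L)
  expect_equal(row$or, direct$or$or, tolerance = 1e-12)
  expect_equal(row$or_pvalue, direct$or$pvalue, tolerance = 1e-12)
  expect_equal(row$study_yes, unname(direct$table["study", "yes"]))
  expect_equal(row$attempts_study_mean, direct$attempts_study$mean, tolerance = 1e-12)
})

test_that("raising p1 moves the competence crossing earlier for clean records", {
  # widening the hypothesis gap lifts the lower line, so an all-success
  # trainee is declared competent no later under the larger p1
  p1s <- c(0.20, 0.30, 0.40, 0.50)
  crossings <- vapply(p1s, function(p1) {
    k <- sprt_constants(failure_rates(0.10, p1))
    classify_competence(make_series(rep(0, 60)), k)$crossing_attempt
  }, integer(1))
  expect_true(all(diff(crossings) <= 0))

  # but the effect is not monotone pathwise: raising p1 also lowers the
  # early upper line, so a trainee with early failures can flip from
  # competent to unacceptable (first-crossing verdicts are not nested)
  sc <- c(1, 0, 1, rep(0, 18))
  expect_equal(classify_competence(make_series(sc),
                                   sprt_constants(failure_rates(0.10, 0.30)))$status,
               "competent")
  expect_equal(classify_competence(make_series(sc),
                                   sprt_constants(failure_rates(0.10, 0.40)))$status,
               "unacceptable")

  rec <- read_attempts(fixture_path())
  expect_error(sensitivity_grid(rec, data.frame(p0 = 0.3, p1 = 0.2)), "p0 < p1")
  expect_error(sensitivity_grid(rec, data.frame(p0 = numeric(), p1 = numeric())),
               "non-empty")
})
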