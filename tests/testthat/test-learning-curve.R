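k_primary <- sprt_constants(failure_rates(0.10, 0.30, 0.10, 0.10))

test_that("build_series orders attempts and accumulates failures", {
  rec <- data.frame(trainee_id = "t1", group = "study",
                    attempt_no = c(3, 1, 4, 2), score = c(1, 0, 0, 0))
  s <- build_series(rec)
  expect_equal(s$scores, c(0L, 0L, 1L, 0L))
  expect_equal(s$cumsum, c(0L, 0L, 1L, 1L))

  s0 <- make_series(rep(0, 25))
  expect_true(all(s0$cumsum == 0L))
  expect_equal(s0$cumsum[25], 0L)
})

test_that("build_series rejects malformed trainee records", {
  expect_error(build_series(data.frame(trainee_id = character(),
                                       group = character(),
                                       attempt_no = integer(),
                                       score = integer())),
               "empty")
  expect_error(build_series(data.frame(trainee_id = "t", group = "g",
                                       attempt_no = c(1, 3), score = c(0, 0))),
               "gaps or duplicates")
  expect_error(build_series(data.frame(trainee_id = "t", group = "g",
                                       attempt_no = c(1, 1, 2), score = 0)),
               "gaps or duplicates")
  expect_error(build_series(data.frame(trainee_id = "t", group = "g",
                                       attempt_no = 1:3, score = c(0, 2, 1))),
               "non-binary")
  expect_error(build_series(data.frame(trainee_id = c("a", "b"), group = "g",
                                       attempt_no = 1, score = 0)),
               "more than one trainee")
})

test_that("classification matches closed-form crossings at the primary setting", {
  # all-success: first n with s*n - b/(P+Q) >= 0 is ceiling(1.62766/0.18617) = 9
  r <- classify_competence(make_series(rep(0, 12)), k_primary)
  expect_equal(r$status, "competent")
  expect_equal(r$crossing_attempt, 9L)

  # short mixed series never reaches either line
  r <- classify_competence(make_series(c(0, 1, 0)), k_primary)
  expect_equal(r$status, "indeterminate")
  expect_true(is.na(r$crossing_attempt))

  # all-failure series crosses the upper line; verdict and attempt must match
  # the independent exhaustive scan
  sc <- rep(1, 50)
  r <- classify_competence(make_series(sc), k_primary)
  o <- oracle_classify(sc, k_primary)
  expect_equal(r$status, "unacceptable")
  expect_equal(r$status, o$status)
  expect_equal(r$crossing_attempt, o$crossing)
})

test_that("classification agrees with the exhaustive scan on random series", {
  set.seed(401)
  settings <- list(c(0.10, 0.30), c(0.10, 0.40), c(0.20, 0.30),
                   c(0.05, 0.20), c(0.20, 0.40))
  ks <- lapply(settings, function(p)
    sprt_constants(failure_rates(p[1], p[2], 0.10, 0.10)))
  for (i in 1:400) {
    sc <- random_scores(200L)
    k <- ks[[(i %% length(ks)) + 1L]]
    got <- classify_competence(make_series(sc), k)
    ref <- oracle_classify(sc, k)
    expect_identical(got$status, ref$status)
    expect_equal(got$crossing_attempt, as.integer(ref$crossing))
  }
})

test_that("turning any failure into a success never harms the trainee", {
  # competent stays competent with a crossing at least as early; the verdict
  # never worsens towards indeterminate/unacceptable
  rank_status <- function(s) match(s, c("unacceptable", "indeterminate", "competent"))
  set.seed(402)
  for (i in 1:60) {
    sc <- random_scores(80L)
    if (!any(sc == 1)) next
    base <- classify_competence(make_series(sc), k_primary)
    flip <- sample(which(sc == 1), 1)
    sc2 <- sc; sc2[flip] <- 0L
    mod <- classify_competence(make_series(sc2), k_primary)
    expect_gte(rank_status(mod$status), rank_status(base$status))
    if (base$status == "competent" && mod$status == "competent")
      expect_lte(mod$crossing_attempt, base$crossing_attempt)
  }
})

test_that("a sustained failure rate at or below p0 is eventually declared competent", {
  set.seed(403)
  for (i in 1:20) {
    sc <- rbinom(600, 1, 0.05)   # well below p0 = 0.10
    r <- classify_competence(make_series(sc), k_primary)
    expect_equal(r$status, "competent")
  }
})

test_that("attempts_to_competence summarises competent trainees only", {
  df <- data.frame(status = rep("competent", 3), crossing_attempt = c(9, 9, 9))
  s <- attempts_to_competence(df)
  expect_equal(s$mean, 9); expect_equal(s$sd, 0); expect_equal(s$n, 3L)

  s <- attempts_to_competence(data.frame(status = c("competent", "competent"),
                                         crossing_attempt = c(10, 20)))
  expect_equal(s$mean, 15)
  expect_equal(s$sd, sqrt(50), tolerance = 1e-9)  # 7.0711

  df <- data.frame(status = c("indeterminate", "competent", "unacceptable"),
                   crossing_attempt = c(NA, 12, 4))
  s <- attempts_to_competence(df)
  expect_equal(s$mean, 12); expect_equal(s$n, 1L)
  expect_equal(s$sd, 0); expect_true(s$degenerate)

  s <- attempts_to_competence(data.frame(status = "indeterminate",
                                         crossing_attempt = NA_integer_))
  expect_equal(s$n, 0L)
  expect_true(is.na(s$mean))
  expect_true(s$degenerate)
})

test_that("chart tables carry the cumulative count and both lines", {
  s <- make_series(c(0, 1, 0, 0, 1))
  tab <- chart_table(s, k_primary)
  expect_equal(names(tab), c("n", "cum_failures", "h0", "h1"))
  expect_equal(tab$cum_failures, c(0, 1, 1, 1, 2))
  expect_equal(tab$h1 - tab$h0,
               rep((k_primary$a + k_primary$b) / (k_primary$P + k_primary$Q), 5),
               tolerance = 1e-12)
})
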