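#' Latent learning-curve model for a simulated trainee
#'
#' Describes a trainee whose per-attempt failure probability declines
#' exponentially with experience:
#' \deqn{p(i) = p_{floor} + (p_{start} - p_{floor}) e^{-(i-1)/\tau_t},}
#' where the trainee-specific time constant is `tau_t = tau * exp(e)` with
#' `e ~ Normal(0, heterogeneity_sd)`, so trainees vary in learning speed on
#' the log scale. Each attempt outcome is then a Bernoulli draw at `p(i)`.
#'
#' The package defaults emulate a six-month obstetric-anaesthesia rotation:
#' 60 attempts per trainee, a starting failure probability of 0.5 for a
#' supervised novice, an asymptotic rate of 0.02 for a proficient operator,
#' and a log-normal spread of 0.35 in learning speed. With these values,
#' time constants of about 4 and 9 attempts produce cohort achievement
#' proportions near 67% and 38% under the (0.10, 0.30, 0.10, 0.10) chart.
#'
#' @param p_start Failure probability at the first attempt, in `[0, 1]`.
#' @param p_floor Asymptotic failure probability, `0 <= p_floor <= p_start`.
#' @param tau Learning time constant, in attempts; positive.
#' @param n_attempts Attempts available in the rotation; at least 1.
#' @param heterogeneity_sd Standard deviation of the per-trainee log-tau
#'   perturbation; non-negative.
#' @return An object of class `"learner_model"`.
#' @export
learner_model <- function(p_start = 0.5, p_floor = 0.02, tau = 4,
                          n_attempts = 60L, heterogeneity_sd = 0.35) {
  if (!(p_floor >= 0 && p_floor <= p_start && p_start <= 1))
    stop("require 0 <= p_floor <= p_start <= 1", call. = FALSE)
  if (!(tau > 0)) stop("'tau' must be positive", call. = FALSE)
  if (!(n_attempts >= 1)) stop("'n_attempts' must be at least 1", call. = FALSE)
  if (heterogeneity_sd < 0) stop("'heterogeneity_sd' must be non-negative", call. = FALSE)
  structure(list(p_start = p_start, p_floor = p_floor, tau = tau,
                 n_attempts = as.integer(n_attempts),
                 heterogeneity_sd = heterogeneity_sd),
            class = "learner_model")
}

#' Two-arm cohort design for the simulator
#'
#' @param n_per_group Trainees per arm; at least 1. Default 21.
#' @param study_model,control_model [learner_model()] objects for the two
#'   arms. Defaults: time constants 4 (study) and 9 (control), other
#'   parameters shared, which put cohort achievement near 67% vs 38% at the
#'   (0.10, 0.30, 0.10, 0.10) setting.
#' @param seed Integer seed controlling the whole cohort; per-trainee
#'   substreams are derived from it (see [simulate_cohort()]).
#' @return An object of class `"cohort_design"`.
#' @export
cohort_design <- function(n_per_group = 21L,
                          study_model = learner_model(tau = 4),
                          control_model = learner_model(tau = 9),
                          seed = 1L) {
  if (!(n_per_group >= 1)) stop("'n_per_group' must be at least 1", call. = FALSE)
  stopifnot(inherits(study_model, "learner_model"),
            inherits(control_model, "learner_model"))
  structure(list(n_per_group = as.integer(n_per_group),
                 study_model = study_model, control_model = control_model,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

# Counter-based substream derivation: trainee k (1-based) in arm g
# (study = 0, control = 1) under master seed S gets its own RNG seed.
# Additive in (g, k), so enlarging a cohort never perturbs the data of
# trainees already generated; all arithmetic stays exact in doubles.
trainee_seed <- function(seed, group_idx, k) {
  m <- 2147483647  # 2^31 - 1
  as.integer(((seed %% m) * 48271 + group_idx * 1299709 + k * 7919) %% m) + 1L
}

#' Simulate one trainee's attempt records
#'
#' Draws a trainee-specific learning time constant, then one Bernoulli
#' outcome per attempt with failure probability declining along the
#' exponential learning curve of `model`. Identical seeds reproduce
#' identical sequences bit-for-bit.
#'
#' @param model A [learner_model()].
#' @param trainee_id Identifier for the output records.
#' @param group Cohort label for the output records.
#' @param seed Integer seed for this trainee's substream.
#' @return A data frame of attempt records (`trainee_id`, `group`,
#'   `attempt_no`, `score`).
#' @export
simulate_trainee <- function(model, trainee_id, group, seed) {
  stopifnot(inherits(model, "learner_model"))
  set.seed(seed)
  eps <- if (model$heterogeneity_sd > 0)
    stats::rnorm(1, 0, model$heterogeneity_sd) else 0
  tau_t <- model$tau * exp(eps)
  i <- seq_len(model$n_attempts)
  p <- model$p_floor + (model$p_start - model$p_floor) * exp(-(i - 1) / tau_t)
  p <- pmin(pmax(p, 0), 1)
  data.frame(trainee_id = as.character(trainee_id),
             group = as.character(group),
             attempt_no = i,
             score = stats::rbinom(model$n_attempts, 1, p),
             stringsAsFactors = FALSE)
}

#' Simulate a two-arm cohort
#'
#' Generates `n_per_group` trainees per arm from the arm's learner model.
#' Each trainee uses an RNG substream derived from the design seed by a
#' counter on (arm, trainee index), so the same design and seed always
#' reproduce the same records and adding trainees leaves earlier trainees'
#' data unchanged.
#'
#' @param design A [cohort_design()].
#' @return A data frame of attempt records for all trainees; study trainees
#'   are labelled `study` with ids `S01, S02, ...`, controls `control` with
#'   ids `C01, C02, ...`.
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  n <- design$n_per_group
  wid <- max(2L, nchar(as.character(n)))
  arm <- function(model, prefix, group, gidx) {
    lapply(seq_len(n), function(k) {
      simulate_trainee(model,
                       sprintf("%s%0*d", prefix, wid, k), group,
                       trainee_seed(design$seed, gidx, k))
    })
  }
  out <- do.call(rbind, c(arm(design$study_model, "S", "study", 0L),
                          arm(design$control_model, "C", "control", 1L)))
  rownames(out) <- NULL
  out
}

#' Operating characteristics of the chart at a constant failure rate
#'
#' Monte-Carlo estimate of the chart's classification probabilities when a
#' trainee's true failure probability is constant: the empirical analogue
#' of the designed error rates. At `failure_rate = p0` the unacceptable
#' proportion approximates the type I error; at `failure_rate = p1` the
#' competent proportion approximates the type II error (both inflated
#' slightly by the discreteness of the counts and truncation at
#' `n_attempts`).
#'
#' @param failure_rate True per-attempt failure probability, constant.
#' @param rates A [failure_rates()] object defining the boundaries.
#' @param n_attempts Attempts per simulated trainee. Default 300.
#' @param n_reps Number of simulated trainees. Default 10000.
#' @param seed RNG seed.
#' @return A list with `prop_competent`, `prop_unacceptable`,
#'   `prop_indeterminate`, plus `n_reps` and `n_attempts`.
#' @export
operating_characteristics <- function(failure_rate, rates, n_attempts = 300L,
                                      n_reps = 10000L, seed = 1L) {
  if (!(failure_rate >= 0 && failure_rate <= 1))
    stop("'failure_rate' must be a probability", call. = FALSE)
  if (n_reps < 1) stop("'n_reps' must be at least 1", call. = FALSE)
  k <- sprt_constants(rates)
  n <- seq_len(n_attempts)
  h0 <- k$s * n - k$h0_intercept
  h1 <- k$s * n + k$h1_intercept

  set.seed(seed)
  scores <- matrix(stats::rbinom(n_attempts * n_reps, 1, failure_rate),
                   nrow = n_attempts)
  cs <- apply(scores, 2, cumsum)
  if (n_attempts == 1L) cs <- matrix(cs, nrow = 1L)
  first_true <- function(m) apply(m, 2, function(z) {
    w <- which(z); if (length(w)) w[1L] else Inf
  })
  fl <- first_true(cs <= h0)
  fh <- first_true(cs >= h1)
  competent    <- is.finite(fl) & fl <= fh
  unacceptable <- !competent & is.finite(fh)
  list(prop_competent = mean(competent),
       prop_unacceptable = mean(unacceptable),
       prop_indeterminate = mean(!competent & !unacceptable),
       n_reps = n_reps, n_attempts = n_attempts)
}

#' Replicate the cohort comparison to estimate detection power
#'
#' Simulates `n_reps` independent two-arm cohorts from `design`, classifies
#' every trainee at the given failure-rate setting, and records the crude
#' odds ratio and the IRLS logistic p-value for each replicate. Used for
#' simulation-based power estimation: the fraction of replicates with
#' p < 0.05 estimates the power at the design's effect size and group size.
#'
#' @param design A [cohort_design()]; its `seed` anchors the replicate
#'   substreams (replicate r uses master seed `seed + r * 1000003` reduced
#'   mod 2^31-1).
#' @param rates A [failure_rates()] object. Default (0.10, 0.30, 0.10, 0.10).
#' @param n_reps Number of replicate cohorts. Default 500.
#' @return A data frame with one row per replicate: `rep`, `study_yes`,
#'   `control_yes`, `or` (crude, with continuity correction when a cell is
#'   0), `pvalue` (logistic; crude log-OR z when the logistic fit separates),
#'   `separation`.
#' @export
simulate_power <- function(design, rates = failure_rates(0.10, 0.30),
                           n_reps = 500L) {
  stopifnot(inherits(design, "cohort_design"))
  k <- sprt_constants(rates)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    d <- design
    d$seed <- as.integer((design$seed + r * 1000003) %% 2147483647)
    rec <- simulate_cohort(d)
    cls <- classify_cohort(rec, k)
    is_study <- cls$group == "study"
    ach <- cls$status == "competent"
    sy <- sum(ach & is_study);  sn <- sum(!ach & is_study)
    cy <- sum(ach & !is_study); cn <- sum(!ach & !is_study)
    or <- odds_ratio_2x2(sy, sn, cy, cn)
    lg <- logistic_or(as.numeric(ach),
                      ifelse(is_study, "study", "control"))
    p <- if (isTRUE(lg$separation)) or$pvalue else lg$pvalue
    rows[[r]] <- data.frame(rep = r, study_yes = sy, control_yes = cy,
                            or = or$or, pvalue = p,
                            separation = isTRUE(lg$separation))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
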