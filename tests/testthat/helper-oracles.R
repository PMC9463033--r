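# Independent oracles used across the suite.

# Exhaustive per-attempt scan: evaluates both boundary inequalities at every
# attempt with its own running total, no early exit, no vectorised trick.
# Recomputes the line values from the raw constants a, b, P, Q.
oracle_classify <- function(scores, constants) {
  a <- constants$a; b <- constants$b
  P <- constants$P; Q <- constants$Q
  slope <- Q / (P + Q)
  total <- 0L
  first_lo <- Inf
  first_hi <- Inf
  for (n in seq_along(scores)) {
    total <- total + scores[n]
    low  <- slope * n - b / (P + Q)
    high <- slope * n + a / (P + Q)
    if (is.infinite(first_lo) && total <= low)  first_lo <- n
    if (is.infinite(first_hi) && total >= high) first_hi <- n
  }
  if (is.finite(first_lo) && first_lo <= first_hi)
    list(status = "competent", crossing = first_lo)
  else if (is.finite(first_hi))
    list(status = "unacceptable", crossing = first_hi)
  else
    list(status = "indeterminate", crossing = NA_integer_)
}

# Boundaries obtained by solving the classical Wald SPRT inequalities
#   ln(beta/(1-alpha)) < LLR_n < ln((1-beta)/alpha),
#   LLR_n = S_n * P - (n - S_n) * Q,
# for the cumulative failure count S_n.
wald_boundaries <- function(p0, p1, alpha, beta, n) {
  P <- log(p1 / p0); Q <- log((1 - p0) / (1 - p1))
  lower_thr <- log(beta / (1 - alpha))     # accept H0 at or below
  upper_thr <- log((1 - beta) / alpha)     # reject H0 at or above
  list(h0 = (lower_thr + n * Q) / (P + Q),
       h1 = (upper_thr + n * Q) / (P + Q))
}

make_series <- function(scores, id = "t", group = "study") {
  build_series(data.frame(trainee_id = id, group = group,
                          attempt_no = seq_along(scores),
                          score = as.integer(scores)))
}

# random trainee series with mixed lengths and failure rates
random_scores <- function(max_len = 200L) {
  n <- sample.int(max_len, 1L)
  rbinom(n, 1L, runif(1, 0.02, 0.6))
}

fixture_path <- function() {
  system.file("extdata", "synthetic_example_cohort.csv", package = "cusumlc",
              mustWork = TRUE)
}
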