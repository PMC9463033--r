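#' SPRT design parameters for a cumulative-failure chart
#'
#' Bundles the four quantities that define a sequential probability ratio
#' test on binary procedure outcomes: the acceptable failure rate `p0`
#' (performance consistent with competence), the unacceptable failure rate
#' `p1`, and the type I / type II error rates `alpha` and `beta`.
#'
#' @param p0 Acceptable failure rate, a probability with `0 < p0 < p1`.
#' @param p1 Unacceptable failure rate, a probability with `p0 < p1 < 1`.
#' @param alpha Type I (false-positive) error rate, in (0, 1). Default 0.10.
#' @param beta Type II (false-negative) error rate, in (0, 1). Default 0.10.
#'
#' @return An object of class `"failure_rates"`: a list with elements
#'   `p0`, `p1`, `alpha`, `beta`.
#' @examples
#' failure_rates(0.10, 0.30)
#' @export
failure_rates <- function(p0, p1, alpha = 0.10, beta = 0.10) {
  for (nm in c("p0", "p1", "alpha", "beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (!(p0 > 0)) stop("invalid failure rates: require 0 < p0 (got p0 = ", p0, ")", call. = FALSE)
  if (!(p1 < 1)) stop("invalid failure rates: require p1 < 1 (got p1 = ", p1, ")", call. = FALSE)
  if (!(p0 < p1)) stop("invalid failure rates: require p0 < p1 (got p0 = ", p0,
                       ", p1 = ", p1, ")", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("invalid error rate: require 0 < alpha < 1", call. = FALSE)
  if (!(beta > 0 && beta < 1)) stop("invalid error rate: require 0 < beta < 1", call. = FALSE)
  structure(list(p0 = p0, p1 = p1, alpha = alpha, beta = beta),
            class = "failure_rates")
}

#' @export
print.failure_rates <- function(x, ...) {
  cat("SPRT failure-rate design\n")
  cat(sprintf("  acceptable rate   p0 = %g\n", x$p0))
  cat(sprintf("  unacceptable rate p1 = %g\n", x$p1))
  cat(sprintf("  error rates    alpha = %g, beta = %g\n", x$alpha, x$beta))
  invisible(x)
}

#' Derived SPRT constants and control-line coefficients
#'
#' Evaluates the intermediate quantities of the sequential probability ratio
#' test for binary failures, using natural logarithms throughout:
#' \deqn{a = \ln[(1-\beta)/\alpha], \quad b = \ln[(1-\alpha)/\beta],}
#' \deqn{P = \ln(p_1/p_0), \quad Q = \ln[(1-p_0)/(1-p_1)], \quad s = Q/(P+Q).}
#' The cumulative-failure chart's control lines have common slope `s`
#' (failures per attempt) and intercepts `-b/(P+Q)` (lower, acceptable line)
#' and `+a/(P+Q)` (upper, unacceptable line).
#'
#' Under the design invariants (`0 < p0 < p1 < 1`, error rates in (0,1) and
#' below 1/2 as usual), all of `a`, `b`, `P`, `Q` are positive and
#' `p0 < s < p1`.
#'
#' @param rates A [failure_rates()] object (or a list with the same fields).
#' @return An object of class `"sprt_constants"`: a list with elements
#'   `a`, `b`, `P`, `Q`, `s`, `h0_intercept` (= b/(P+Q)),
#'   `h1_intercept` (= a/(P+Q)) and the originating `rates`.
#' @examples
#' k <- sprt_constants(failure_rates(0.10, 0.30, 0.10, 0.10))
#' k$s          # boundary slope, about 0.186 failures/attempt
#' @seealso [boundary_values()] for the control lines at given attempt numbers.
#' @export
sprt_constants <- function(rates) {
  if (!inherits(rates, "failure_rates"))
    rates <- failure_rates(rates$p0, rates$p1, rates$alpha, rates$beta)
  a <- log((1 - rates$beta) / rates$alpha)
  b <- log((1 - rates$alpha) / rates$beta)
  P <- log(rates$p1 / rates$p0)
  Q <- log((1 - rates$p0) / (1 - rates$p1))
  s <- Q / (P + Q)
  structure(
    list(a = a, b = b, P = P, Q = Q, s = s,
         h0_intercept = b / (P + Q),
         h1_intercept = a / (P + Q),
         rates = rates),
    class = "sprt_constants"
  )
}

#' @export
format.sprt_constants <- function(x, digits = 10, ...) {
  # flat key = value block, suitable for inclusion in plain-text reports
  keys <- c("p0", "p1", "alpha", "beta", "a", "b", "P", "Q", "s",
            "h0_intercept", "h1_intercept")
  vals <- c(x$rates$p0, x$rates$p1, x$rates$alpha, x$rates$beta,
            x$a, x$b, x$P, x$Q, x$s, x$h0_intercept, x$h1_intercept)
  sprintf("%s = %s", format(keys, width = 12), format(vals, digits = digits))
}

#' @export
print.sprt_constants <- function(x, ...) {
  cat("SPRT constants (cumulative-failure chart)\n")
  cat(format(x), sep = "\n")
  cat(sprintf("lines: h0(n) = %.5f n - %.5f   (acceptable)\n", x$s, x$h0_intercept))
  cat(sprintf("       h1(n) = %.5f n + %.5f   (unacceptable)\n", x$s, x$h1_intercept))
  invisible(x)
}

#' Control-line values at given attempt numbers
#'
#' The lower (acceptable-performance) and upper (unacceptable-performance)
#' boundaries of the cumulative-failure chart at attempt number `n`:
#' `h0(n) = s*n - b/(P+Q)` and `h1(n) = s*n + a/(P+Q)`. A trainee's
#' cumulative failure count is declared acceptable on first falling to or
#' below `h0`, unacceptable on first rising to or above `h1`.
#'
#' @param constants An [sprt_constants()] object.
#' @param n Attempt number(s); positive integers (vectorised).
#' @return A data frame with columns `n`, `h0`, `h1` (failures).
#' @examples
#' k <- sprt_constants(failure_rates(0.10, 0.30))
#' boundary_values(k, 1:10)
#' @export
boundary_values <- function(constants, n) {
  stopifnot(inherits(constants, "sprt_constants"))
  if (length(n) == 0L || !is.numeric(n) || any(!is.finite(n)) ||
      any(n < 1) || any(n != floor(n)))
    stop("'n' must contain positive integer attempt numbers (n >= 1)", call. = FALSE)
  data.frame(
    n  = as.integer(n),
    h0 = constants$s * n - constants$h0_intercept,
    h1 = constants$s * n + constants$h1_intercept
  )
}
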