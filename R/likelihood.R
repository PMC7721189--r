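#' Token-allocation probabilities per unit
#'
#' Probability that one token lands in unit `i`:
#' `p_i = x_i A_i^(beta-1) / Z(beta)` with normalisation
#' `Z(beta) = sum_i x_i A_i^(beta-1)`. At `beta = 1` this is the per-capita
#' allocation `x_i / X` regardless of the kernel. Computed in log space with
#' log-sum-exp: populations and attractiveness span many orders of magnitude
#' and `beta` up to 2 overflows naive powers.
#'
#' @param x positive populations.
#' @param A attractiveness vector (elementwise `>= x`), see
#'   [attractiveness()].
#' @param beta scaling exponent, inside the prior support `[0, 2]`.
#' @param log return log-probabilities?
#' @return Probability vector of length `N` summing to 1 (or its log).
#' @examples
#' city_token_probabilities(c(100, 300), A = c(100, 300), beta = 2)
#' @export
city_token_probabilities <- function(x, A, beta, log = FALSE) {
  check_beta(beta)
  stopifnot(length(x) == length(A), all(x > 0), all(A > 0))
  lp <- log(x) + (beta - 1) * log(A)
  lp <- lp - logsumexp(lp)
  if (log) lp else exp(lp)
}

check_beta <- function(beta) {
  if (length(beta) != 1L || !is.finite(beta) || beta < 0 || beta > 2)
    stop("beta must be a single value in the prior support [0, 2]")
  invisible(beta)
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Expected token counts
#'
#' `E[y_i] = Y p_i`; at `beta = 1` this is the per-capita line `Y x_i / X`.
#'
#' @param system a [city_system()] with observed counts (supplies `Y`), or a
#'   single number taken as the token total `Y`.
#' @param p probability vector on the simplex.
#' @return Vector of expected counts, summing to `Y`.
#' @export
expected_tokens <- function(system, p) {
  Y <- if (inherits(system, "city_system")) system$Y else as.numeric(system)
  stopifnot(is.finite(Y), abs(sum(p) - 1) < 1e-8)
  Y * p
}

#' Multinomial log-likelihood of the observed counts
#'
#' Log-probability of the observed allocation `y` under the generative model:
#' `ln Y! - sum_i ln y_i! + sum_i y_i ln p_i`, with factorials through
#' `lgamma(. + 1)` so that non-integer counts (GDP, road miles) define a
#' consistent quasi-likelihood -- the multinomial coefficient does not depend
#' on the model or its parameters, so it cancels from every model comparison.
#'
#' Units with `y_i = 0` contribute nothing (`p_i > 0` always since `x_i > 0`),
#' which is precisely what the conventional log-log regression cannot handle.
#'
#' @param system a [city_system()] with counts.
#' @param A attractiveness vector for the kernel under consideration.
#' @param beta scaling exponent in `[0, 2]`.
#' @param terms `"full"` for the complete log-likelihood, `"model"` for only
#'   the model-dependent term `sum_i y_i ln p_i` (the part that varies across
#'   kernels and parameters).
#' @return A single number (natural log).
#' @examples
#' sys <- city_system(c("a", "b"), c(0, 1), c(0, 0), c(100, 300),
#'                    count = c(1, 1))
#' log_likelihood(sys, A = sys$x, beta = 1)   # log(0.375)
#' @export
log_likelihood <- function(system, A, beta, terms = c("full", "model")) {
  terms <- match.arg(terms)
  if (is.null(system$y)) stop("system has no observed counts")
  lp <- city_token_probabilities(system$x, A, beta, log = TRUE)
  model_term <- sum(system$y * lp)
  if (terms == "model") return(model_term)
  multinomial_log_coefficient(system$y) + model_term
}

# ln Y! - sum ln y_i!, via lgamma for continuous counts
multinomial_log_coefficient <- function(y) {
  lgamma(sum(y) + 1) - sum(lgamma(y + 1))
}
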