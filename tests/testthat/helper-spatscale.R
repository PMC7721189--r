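# shared fixtures, all built in code

# the two-unit worked example: x = (100, 300), 10 km apart
two_unit_system <- function(y = NULL) {
  city_system(c("a", "b"), lat = c(10, 10), lon = c(20, 20.2),
              population = c(100, 300), count = y)
}

two_unit_dist <- function(d12 = 10) {
  m <- matrix(c(0, d12, d12, 0), 2, 2)
  dimnames(m) <- list(c("a", "b"), c("a", "b"))
  m
}

# seeded random system + distances; uniform placement unless clustered
random_system <- function(n = 30, seed = 1, Y = NULL, clustered = FALSE,
                          ...) {
  sys <- sample_city_system(n, seed = seed,
                            n_clusters = if (clustered) 25 else 0, ...)
  d <- distance_matrix(sys)
  if (!is.null(Y)) {
    y <- sample_tokens(sys, d, "P", Y = Y, seed = seed + 1000L)
    sys <- with_counts(sys, y)
  }
  list(system = sys, dist = d)
}

# direct, naive evaluation of the allocation probabilities (independent of
# the log-space implementation): p_i = x_i A_i^(b-1) / sum
naive_probs <- function(x, A, beta) {
  u <- x * A^(beta - 1)
  u / sum(u)
}

# all compositions of total Y over n cells
compositions <- function(Y, n) {
  if (n == 1L) return(matrix(Y, 1, 1))
  out <- list()
  for (k in 0:Y) {
    rest <- compositions(Y - k, n - 1L)
    out[[length(out) + 1L]] <- cbind(k, rest)
  }
  unname(do.call(rbind, out))
}
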