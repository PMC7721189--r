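#' Maximum-likelihood scaling exponent at fixed kernel
#'
#' Maximises the multinomial log-likelihood over the scaling exponent
#' `beta` in the prior support `[0, 2]`, with the attractiveness `A` (hence
#' the interaction range `alpha`) held fixed. The log-likelihood is concave in
#' `beta` -- it is linear in `beta` minus `Y` times a log-sum-exp of linear
#' functions -- so the maximiser is unique and is found by bracketed
#' root-finding on the score
#' `dl/dbeta = sum_i y_i ln A_i - Y E_beta[ln A]`.
#' A maximum on the edge of the support is returned as `beta = 0` or `2` with
#' a boundary flag. When all `A_i` are (numerically) equal the likelihood is
#' flat in `beta`; `beta = 1` is returned flagged as unidentifiable.
#'
#' @param system a [city_system()] with observed counts.
#' @param A attractiveness vector, see [attractiveness()].
#' @param tol absolute tolerance on `beta`.
#' @return A list with `beta_hat`, `loglik` (full log-likelihood at the
#'   optimum), `boundary` (`"none"`, `"lower"` or `"upper"`) and
#'   `identifiable` (logical).
#' @export
fit_beta <- function(system, A, tol = 1e-6) {
  if (is.null(system$y)) stop("system has no observed counts")
  if (system$N < 2L) stop("beta is unidentifiable with fewer than 2 units")
  res <- fit_beta_core(system$x, A, system$y, tol)
  res$loglik <- res$loglik + multinomial_log_coefficient(system$y)
  res
}

# core fitter on raw vectors; loglik returned WITHOUT the multinomial
# coefficient (it is model-independent and the bootstrap refits only need the
# maximiser)
fit_beta_core <- function(x, A, y, tol = 1e-6) {
  lx <- log(x); lA <- log(A); Y <- sum(y)
  # flat in beta when even the extreme beta swing cannot move the
  # log-likelihood by a meaningful amount (e.g. alpha far beyond the
  # system diameter, where A is constant and the P model is recovered)
  flat <- diff(range(lA)) * 2 * Y < 1e-6
  model_term <- function(beta) {
    lp <- lx + (beta - 1) * lA
    sum(y * (lp - logsumexp(lp)))
  }
  if (flat)
    return(list(beta_hat = 1, loglik = model_term(1),
                boundary = "none", identifiable = FALSE))
  Sy <- sum(y * lA)
  score <- function(beta) {
    lp <- lx + (beta - 1) * lA
    p <- exp(lp - logsumexp(lp))
    Sy - Y * sum(p * lA)
  }
  s0 <- score(0); s2 <- score(2)
  if (s0 <= 0) {
    beta_hat <- 0; boundary <- "lower"
  } else if (s2 >= 0) {
    beta_hat <- 2; boundary <- "upper"
  } else {
    beta_hat <- stats::uniroot(score, c(0, 2), tol = tol)$root
    boundary <- "none"
  }
  list(beta_hat = beta_hat, loglik = model_term(beta_hat),
       boundary = boundary, identifiable = TRUE)
}

#' Default search grid for the interaction range
#'
#' `{0}` followed by `n` log-spaced values from `min_km` to `alpha_max`.
#' Log-spacing reflects that the interaction scales of interest (tens of km,
#' the range over which people plausibly interact) sit far below the prior
#' upper bound of one Earth radius.
#'
#' @param alpha_max upper bound in km (default 6371).
#' @param n number of positive grid points.
#' @param min_km smallest positive grid point in km.
#' @return Numeric vector of length `n + 1` starting at 0.
#' @export
default_alpha_grid <- function(alpha_max = 6371, n = 60, min_km = 0.1) {
  c(0, exp(seq(log(min_km), log(alpha_max), length.out = n)))
}

#' Profile the likelihood over the interaction range
#'
#' For each `alpha` in the grid: compute the attractiveness once, then
#' maximise over `beta`. This is the efficient access pattern -- for fixed
#' `alpha` the whole distance matrix collapses into the vector `A`.
#'
#' @param system a [city_system()] with counts.
#' @param dist distance matrix in km.
#' @param family `"G"` or `"E"`.
#' @param alpha_grid increasing vector of `alpha` values in km (may include
#'   0, which is evaluated as the city kernel).
#' @return A data frame with columns `alpha`, `beta_hat`, `loglik`,
#'   `boundary`, `identifiable`, one row per grid point.
#' @export
profile_alpha <- function(system, dist, family = c("G", "E"),
                          alpha_grid = default_alpha_grid()) {
  family <- match.arg(family)
  if (length(alpha_grid) == 0L) stop("alpha_grid must not be empty")
  rows <- lapply(alpha_grid, function(a) {
    A <- attractiveness(system, dist, family, a)
    f <- fit_beta(system, A)
    data.frame(alpha = a, beta_hat = f$beta_hat, loglik = f$loglik,
               boundary = f$boundary, identifiable = f$identifiable)
  })
  do.call(rbind, rows)
}

#' Joint MAP fit of one model family
#'
#' Fits one of the four model families:
#' * `"P"` (per capita): no free parameters, `beta` fixed at 1.
#' * `"C"` (city): `beta` fitted with `A = x`.
#' * `"G"`, `"E"`: a coarse log-spaced `alpha` grid (including `alpha = 0`)
#'   is profiled, then the range is refined by bracketed search around the
#'   best grid point to 1\% relative tolerance; `beta` is re-maximised at
#'   every candidate `alpha`. With flat priors the MAP coincides with the
#'   maximum-likelihood fit inside the support.
#'
#' @inheritParams profile_alpha
#' @param family one of `"P"`, `"C"`, `"G"`, `"E"`.
#' @param alpha_grid search grid for families `G`/`E`.
#' @param keep_profile attach the grid profile to the fit?
#' @return A `scaling_fit`: list with `family`, `alpha_hat` (`NA` for P/C),
#'   `beta_hat` (1 for P), `loglik`, `boundary`, `identifiable`,
#'   `sigma_beta` (`NA` until [bootstrap_sigma_beta()] is run) and optionally
#'   `profile`.
#' @export
map_fit <- function(system, dist, family = c("P", "C", "G", "E"),
                    alpha_grid = default_alpha_grid(), keep_profile = TRUE) {
  family <- match.arg(family)
  if (is.null(system$y)) stop("system has no observed counts")
  if (family == "P") {
    ll <- log_likelihood(system, A = system$x, beta = 1)
    return(new_scaling_fit(family, NA_real_, 1, ll, "none", TRUE))
  }
  if (family == "C") {
    f <- fit_beta(system, attractiveness(system, dist, "C"))
    return(new_scaling_fit(family, NA_real_, f$beta_hat, f$loglik,
                           f$boundary, f$identifiable))
  }
  prof <- profile_alpha(system, dist, family, alpha_grid)
  i <- which.max(prof$loglik)
  lo <- if (i > 1L) prof$alpha[i - 1L] else 0
  hi <- if (i < nrow(prof)) prof$alpha[i + 1L] else prof$alpha[i]
  profile_ll <- function(a) {
    A <- attractiveness(system, dist, family, a)
    fit_beta(system, A)$loglik
  }
  alpha_hat <- prof$alpha[i]
  if (hi > lo) {
    opt <- stats::optimize(profile_ll, c(lo, hi), maximum = TRUE,
                           tol = max(0.01 * prof$alpha[i], 0.01 * (hi - lo)))
    # the refined point must actually beat the grid point (optimize can
    # return an interior point when the optimum sits at alpha = 0)
    if (opt$objective > prof$loglik[i]) alpha_hat <- opt$maximum
  }
  f <- fit_beta(system, attractiveness(system, dist, family, alpha_hat))
  fit <- new_scaling_fit(family, alpha_hat, f$beta_hat, f$loglik,
                         f$boundary, f$identifiable)
  if (keep_profile) fit$profile <- prof
  fit
}

new_scaling_fit <- function(family, alpha_hat, beta_hat, loglik,
                            boundary = "none", identifiable = TRUE) {
  structure(list(family = family, alpha_hat = alpha_hat,
                 beta_hat = beta_hat, loglik = loglik,
                 boundary = boundary, identifiable = identifiable,
                 sigma_beta = NA_real_, profile = NULL),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("<scaling_fit> family ", x$family, sep = "")
  if (!is.na(x$alpha_hat)) cat(", alpha =", signif(x$alpha_hat, 4), "km")
  cat(", beta =", signif(x$beta_hat, 4))
  if (!is.na(x$sigma_beta)) cat(" (sigma ", signif(x$sigma_beta, 2), ")",
                                sep = "")
  cat(", loglik =", format(x$loglik))
  if (x$boundary != "none") cat("  [beta at", x$boundary, "boundary]")
  if (!x$identifiable) cat("  [beta unidentifiable: flat likelihood]")
  cat("\n")
  invisible(x)
}

#' Parametric-bootstrap uncertainty of the scaling exponent
#'
#' Draws `B` replicate count vectors `y* ~ Multinomial(Y, p_hat)` from the
#' fitted model, re-estimates `beta` for each (with `alpha` held at its MAP
#' value, so the reported spread is the `beta`-only uncertainty) and returns
#' the sample standard deviation of the replicate estimates. Deterministic
#' given `seed`.
#'
#' @param system a [city_system()] with counts.
#' @param dist distance matrix (km).
#' @param fit a `scaling_fit` from [map_fit()].
#' @param B number of bootstrap replicates (`>= 2`).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return `sigma_beta`, a single number; the replicate estimates are
#'   attached as attribute `"replicates"`.
#' @export
bootstrap_sigma_beta <- function(system, dist, fit, B = 100, seed = NULL) {
  stopifnot(inherits(fit, "scaling_fit"), B >= 2)
  if (fit$family == "P")
    stop("the per-capita model has no free exponent to bootstrap")
  A <- switch(fit$family,
              C = attractiveness(system, dist, "C"),
              attractiveness(system, dist, fit$family, fit$alpha_hat))
  beta0 <- fit$beta_hat
  p <- city_token_probabilities(system$x, A, beta0)
  Y <- system$Y
  if (abs(Y - round(Y)) > 0) {
    warning("non-integer total count Y = ", format(Y),
            "; rounding for multinomial resampling")
    Y <- round(Y)
  }
  reps <- with_seed(seed, {
    ystar <- stats::rmultinom(B, size = Y, prob = p)
    apply(ystar, 2L, function(y) fit_beta_core(system$x, A, y)$beta_hat)
  })
  structure(stats::sd(reps), replicates = reps)
}

# evaluate code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
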