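#' Flat priors for model comparison
#'
#' All four model classes get prior probability 1/4. Within a class the
#' parameter priors are flat on their support: `beta` on `[0, 2]`, the
#' interaction range `alpha` on `[0, alpha_max]` km. The densities are
#' therefore 1 (P, no parameters), 1/2 (C), and `1/(2 alpha_max)` (G, E).
#'
#' @param alpha_max upper bound of the `alpha` prior in km; the default is
#'   one Earth radius, an intentionally generous "distance no longer
#'   matters" scale.
#' @return A `prior_spec` list with `alpha_max`, `log_model_prior`, and the
#'   per-family log parameter densities.
#' @export
prior_spec <- function(alpha_max = 6371) {
  stopifnot(alpha_max > 0)
  structure(list(
    alpha_max = alpha_max,
    log_model_prior = log(1 / 4),
    log_theta_density = c(P = 0, C = log(1 / 2),
                          G = -log(2 * alpha_max), E = -log(2 * alpha_max))),
    class = "prior_spec")
}

#' Marginal log-evidence of one model family
#'
#' The joint log-probability `log P(M, D)` of model class and data, obtained
#' by integrating the likelihood against the flat parameter priors:
#' no integral for P, a 1-D integral over `beta` for C, and a 2-D integral
#' over `(alpha, beta)` for G and E. Quadrature is trapezoidal with
#' log-sum-exp accumulation; since the likelihood concentrates sharply around
#' the maximum for large token totals, the grids combine a coarse sweep of
#' the full support with a dense cluster around the maximum (placed using the
#' local curvature). The whole quadrature is repeated at doubled resolution
#' until the description length changes by less than `tol_bytes`.
#'
#' @param system a [city_system()] with counts.
#' @param dist distance matrix (km).
#' @param family one of `"P"`, `"C"`, `"G"`, `"E"`.
#' @param priors a [prior_spec()].
#' @param resolution integer multiplier on all starting grid sizes.
#' @param tol_bytes convergence tolerance on the description length, bytes.
#' @param max_doublings maximum number of refinement rounds; exceeding it
#'   attaches a `convergence` warning attribute instead of failing.
#' @return `log P(M, D)` (natural log), with attributes `resolution` (the
#'   multiplier at convergence) and `converged`.
#' @export
marginal_log_evidence <- function(system, dist, family = c("P", "C", "G", "E"),
                                  priors = prior_spec(), resolution = 1,
                                  tol_bytes = 0.1, max_doublings = 4) {
  family <- match.arg(family)
  if (is.null(system$y)) stop("system has no observed counts")
  lcoef <- multinomial_log_coefficient(system$y)
  lprior <- priors$log_model_prior + priors$log_theta_density[[family]]
  if (family == "P") {
    lev <- log_likelihood(system, A = system$x, beta = 1) +
      priors$log_model_prior
    return(structure(lev, resolution = resolution, converged = TRUE))
  }
  integral <- function(res) {
    if (family == "C") {
      A <- attractiveness(system, dist, "C")
      beta_log_integral(system, A, resolution = res)
    } else {
      alpha_log_integral(system, dist, family, priors$alpha_max,
                         resolution = res)
    }
  }
  res <- resolution
  prev <- cur <- integral(res)
  # max_doublings = 0 evaluates at exactly the requested resolution,
  # without the convergence check (useful for stability studies)
  converged <- max_doublings == 0L
  for (k in seq_len(max_doublings)) {
    res <- res * 2L
    cur <- integral(res)
    if (abs(cur - prev) / (8 * log(2)) < tol_bytes) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  if (!converged)
    warning("evidence quadrature for family ", family,
            " not converged to ", tol_bytes, " bytes after ",
            max_doublings, " refinements")
  structure(cur + lcoef + lprior, resolution = res, converged = converged)
}

# log integral over beta in [0, 2] of exp(model-term log-likelihood),
# multinomial coefficient excluded (added once by the caller)
beta_log_integral <- function(system, A, resolution = 1) {
  n_coarse <- 32L * resolution + 1L
  n_local <- 40L * resolution + 1L
  x <- system$x; y <- system$y
  lx <- log(x); lA <- log(A)
  ll <- function(beta) {
    lp <- lx + (beta - 1) * lA
    sum(y * (lp - logsumexp(lp)))
  }
  f <- fit_beta_core(x, A, y)
  grid <- seq(0, 2, length.out = n_coarse)
  if (f$identifiable) {
    sigma <- curvature_scale(ll, f$beta_hat, lower = 0, upper = 2)
    if (is.finite(sigma) && sigma < 2) {
      local <- f$beta_hat + sigma * seq(-10, 10, length.out = n_local)
      grid <- c(grid, pmin(2, pmax(0, local)))
    }
  }
  grid <- sort(unique(grid))
  log_trapezoid(grid, vapply(grid, ll, numeric(1)))
}

# log integral over (alpha, beta) in [0, alpha_max] x [0, 2]; inner beta
# integral nested inside an outer trapezoid over alpha
alpha_log_integral <- function(system, dist, family, alpha_max,
                               resolution = 1) {
  n_alpha <- 40L * resolution + 1L
  n_local <- 24L * resolution + 1L
  g <- function(a) {
    A <- attractiveness(system, dist, family, a)
    beta_log_integral(system, A, resolution = resolution)
  }
  grid <- c(0, exp(seq(log(0.01), log(alpha_max), length.out = n_alpha)))
  gv <- vapply(grid, g, numeric(1))
  i <- which.max(gv)
  a_hat <- grid[i]
  if (a_hat > 0) {
    sigma <- curvature_scale(g, a_hat, lower = 0, upper = alpha_max,
                             step = max(1e-3 * a_hat, 1e-3))
    if (is.finite(sigma) && sigma < alpha_max) {
      local <- a_hat + sigma * seq(-10, 10, length.out = n_local)
      local <- local[local > 0 & local < alpha_max]
      if (length(local)) {
        grid2 <- sort(unique(c(grid, local)))
        new_pts <- setdiff(grid2, grid)
        gv <- c(gv, vapply(new_pts, g, numeric(1)))[order(c(grid, new_pts))]
        grid <- grid2
      }
    }
  }
  log_trapezoid(grid, gv)
}

# 1/sqrt(-f'') by central second difference at the maximum (clamped inside
# the support); Inf when the surface is locally flat
curvature_scale <- function(f, at, lower, upper, step = 1e-3) {
  at <- min(max(at, lower + step), upper - step)
  d2 <- (f(at + step) - 2 * f(at) + f(at - step)) / step^2
  if (!is.finite(d2) || d2 >= 0) return(Inf)
  1 / sqrt(-d2)
}

# log of the trapezoid-rule integral of exp(logf) on sorted nodes t
log_trapezoid <- function(t, logf) {
  n <- length(t)
  stopifnot(n >= 2L, !is.unsorted(t))
  w <- c(diff(t)[1] / 2,
         if (n > 2L) (t[3:n] - t[1:(n - 2L)]) / 2,
         diff(t)[n - 1L] / 2)
  keep <- w > 0
  logsumexp(logf[keep] + log(w[keep]))
}

#' Description length in bytes
#'
#' Converts a marginal log-evidence (natural log) to the length of the
#' optimal joint encoding of model and data:
#' `D = -log2 P(M, D) / 8` bytes. Smaller is better; the model-comparison
#' score of the whole framework.
#'
#' @param log_evidence value from [marginal_log_evidence()] (natural log).
#' @return Description length in bytes.
#' @examples
#' description_length(-8 * log(2))  # one byte
#' @export
description_length <- function(log_evidence) {
  stopifnot(all(is.finite(log_evidence)))
  -as.numeric(log_evidence) / (8 * log(2))
}

#' Laplace approximation to the log-evidence
#'
#' Gaussian (Laplace) approximation around an interior MAP:
#' `log L(theta_hat) + log prior + (k/2) log(2 pi) - (1/2) log det(-H)`.
#' Refused (with an error) when the MAP touches a prior boundary -- in
#' particular the `alpha = 0` edge where the flat prior is discontinuous --
#' since the Gaussian picture is invalid there. Intended as a cross-check on
#' the quadrature, not a replacement.
#'
#' @inheritParams marginal_log_evidence
#' @param fit the `scaling_fit` of the same family from [map_fit()].
#' @return Approximate `log P(M, D)` (natural log).
#' @export
laplace_log_evidence <- function(system, dist, fit, priors = prior_spec()) {
  stopifnot(inherits(fit, "scaling_fit"))
  family <- fit$family
  lprior <- priors$log_model_prior + priors$log_theta_density[[family]]
  if (family == "P")
    return(log_likelihood(system, A = system$x, beta = 1) +
             priors$log_model_prior)
  if (fit$boundary != "none" || !fit$identifiable)
    stop("Laplace approximation refused: MAP on the boundary of the prior ",
         "support or likelihood flat")
  if (family %in% c("G", "E") &&
      (fit$alpha_hat <= 0 || fit$alpha_hat >= priors$alpha_max))
    stop("Laplace approximation refused: alpha MAP at a prior ",
         "discontinuity (alpha = 0) or at alpha_max")
  x <- system$x; y <- system$y; lx <- log(x)
  ll_beta <- function(A) {
    lA <- log(A)
    function(beta) {
      lp <- lx + (beta - 1) * lA
      sum(y * (lp - logsumexp(lp)))
    }
  }
  if (family == "C") {
    f <- ll_beta(attractiveness(system, dist, "C"))
    h <- 1e-4
    d2 <- (f(fit$beta_hat + h) - 2 * f(fit$beta_hat) +
             f(fit$beta_hat - h)) / h^2
    if (d2 >= 0) stop("Laplace approximation refused: non-negative curvature")
    return(multinomial_log_coefficient(y) + f(fit$beta_hat) + lprior +
             0.5 * log(2 * pi) - 0.5 * log(-d2))
  }
  ll <- function(a, b) {
    A <- attractiveness(system, dist, family, a)
    ll_beta(A)(b)
  }
  a <- fit$alpha_hat; b <- fit$beta_hat
  ha <- max(1e-4 * a, 1e-5); hb <- 1e-4
  H <- matrix(NA_real_, 2, 2)
  H[1, 1] <- (ll(a + ha, b) - 2 * ll(a, b) + ll(a - ha, b)) / ha^2
  H[2, 2] <- (ll(a, b + hb) - 2 * ll(a, b) + ll(a, b - hb)) / hb^2
  H[1, 2] <- H[2, 1] <-
    (ll(a + ha, b + hb) - ll(a + ha, b - hb) -
       ll(a - ha, b + hb) + ll(a - ha, b - hb)) / (4 * ha * hb)
  detH <- H[1, 1] * H[2, 2] - H[1, 2]^2
  if (detH <= 0 || H[1, 1] >= 0)
    stop("Laplace approximation refused: Hessian not negative definite")
  multinomial_log_coefficient(y) + ll(a, b) + lprior +
    log(2 * pi) - 0.5 * log(detH)
}

#' Compare model families by description length
#'
#' Fits every requested family by MAP, integrates its evidence, converts to
#' description lengths and tabulates `D` and `Delta D` relative to the
#' per-capita model. The conventional log-log straight-line fit is attached
#' for reference (it defines no generative likelihood, hence no `D`).
#' Families whose `D` lies within `tie_tol_bytes` of the winner are flagged
#' as ties: differences of a few bytes are at the edge of what the
#' quadrature (and the modelling itself) can adjudicate.
#'
#' @inheritParams marginal_log_evidence
#' @param families subset of `c("P", "C", "G", "E")`, at least two.
#' @param alpha_grid `alpha` search grid for the G/E MAP fits.
#' @param B bootstrap replicates for `sigma_beta` (0 skips the bootstrap).
#' @param seed seed for the bootstrap.
#' @param tie_tol_bytes tie-flag tolerance in bytes.
#' @return A `scaling_comparison`: list with `table` (one row per family:
#'   `family, alpha_hat, beta_hat, sigma_beta, loglik, log_evidence,
#'   D_bytes, delta_D, post_prob, tie`), `winner`, `linear_fit`, and the
#'   priors used.
#' @export
compare_models <- function(system, dist, families = c("P", "C", "G", "E"),
                           priors = prior_spec(),
                           alpha_grid = default_alpha_grid(priors$alpha_max),
                           B = 0, seed = NULL, tie_tol_bytes = 1,
                           tol_bytes = 0.1) {
  families <- match.arg(families, c("P", "C", "G", "E"), several.ok = TRUE)
  if (length(families) < 2L) stop("need at least two families to compare")
  rows <- lapply(families, function(fam) {
    fit <- map_fit(system, dist, fam, alpha_grid = alpha_grid,
                   keep_profile = FALSE)
    lev <- marginal_log_evidence(system, dist, fam, priors,
                                 tol_bytes = tol_bytes)
    sb <- NA_real_
    if (B > 0 && fam != "P")
      sb <- as.numeric(bootstrap_sigma_beta(system, dist, fit, B = B,
                                            seed = seed))
    data.frame(family = fam, alpha_hat = fit$alpha_hat,
               beta_hat = fit$beta_hat, sigma_beta = sb,
               loglik = fit$loglik, log_evidence = as.numeric(lev),
               D_bytes = description_length(lev))
  })
  tab <- do.call(rbind, rows)
  ref <- if ("P" %in% families) "P" else families[1L]
  tab$delta_D <- tab$D_bytes - tab$D_bytes[tab$family == ref]
  lpost <- tab$log_evidence - logsumexp(tab$log_evidence)
  tab$post_prob <- exp(lpost)
  dmin <- min(tab$D_bytes)
  tab$tie <- tab$D_bytes - dmin <= tie_tol_bytes
  structure(list(table = tab,
                 winner = tab$family[which.min(tab$D_bytes)],
                 reference = ref,
                 linear_fit = if (!is.null(system$y) && any(system$y > 0))
                   loglog_linear_fit(system) else NULL,
                 priors = priors),
            class = "scaling_comparison")
}

#' @export
print.scaling_comparison <- function(x, ...) {
  cat("<scaling_comparison> reference:", x$reference,
      " winner:", x$winner, "\n")
  tab <- x$table
  out <- data.frame(family = tab$family,
                    alpha = signif(tab$alpha_hat, 4),
                    beta = signif(tab$beta_hat, 4),
                    sigma_beta = signif(tab$sigma_beta, 2),
                    D_bytes = round(tab$D_bytes, 1),
                    delta_D = round(tab$delta_D, 1),
                    post_prob = signif(tab$post_prob, 3),
                    tie = ifelse(tab$tie, "*", ""))
  print(out, row.names = FALSE)
  if (!is.null(x$linear_fit))
    cat(sprintf("log-log linear fit: beta = %.4f (%d zero-count unit%s excluded)\n",
                x$linear_fit$beta, x$linear_fit$n_excluded,
                if (x$linear_fit$n_excluded == 1) "" else "s"))
  invisible(x)
}
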