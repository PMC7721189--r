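test_that("description length converts log evidence to bytes", {
  expect_equal(description_length(-8 * log(2)), 1, tolerance = 1e-12)
  # monotone: worse evidence, longer code
  ev <- sort(-stats::rexp(10) * 100)
  expect_true(all(diff(description_length(ev)) < 0))
  # per-capita model on the two-unit worked instance, exact arithmetic
  sys <- two_unit_system(y = c(1, 1))
  lev <- marginal_log_evidence(sys, two_unit_dist(), "P")
  expect_equal(as.numeric(lev), log(0.375) + log(1 / 4), tolerance = 1e-12)
  expect_equal(description_length(lev),
               (-log(0.375) + log(4)) / (8 * log(2)), tolerance = 1e-12)
})

test_that("priors integrate to one and models share mass equally", {
  pr <- prior_spec(alpha_max = 6371)
  expect_equal(exp(pr$log_model_prior) * 4, 1)
  # density x support volume = 1 per family
  expect_equal(exp(pr$log_theta_density[["C"]]) * 2, 1)
  expect_equal(exp(pr$log_theta_density[["G"]]) * 2 * 6371, 1)
  expect_equal(exp(pr$log_theta_density[["E"]]) * 2 * 6371, 1)
})

test_that("quadrature matches a fine-grid Riemann oracle (C family)", {
  rs <- random_system(8, seed = 81)
  y <- sample_tokens(rs$system, rs$dist, "C", beta = 1.4, Y = 50, seed = 82)
  sys <- with_counts(rs$system, y)
  lev <- marginal_log_evidence(sys, rs$dist, "C", tol_bytes = 0.01)
  # independent route: naive probabilities, dmultinom, midpoint Riemann sum
  bgrid <- seq(1e-4 / 2, 2 - 1e-4 / 2, by = 1e-4)
  vals <- vapply(bgrid, function(b) {
    p <- naive_probs(sys$x, sys$x, b)
    stats::dmultinom(sys$y, prob = p)
  }, numeric(1))
  oracle <- log(sum(vals) * 1e-4 * (1 / 2)) + log(1 / 4)
  expect_equal(as.numeric(lev), oracle,
               tolerance = 0.05 * 8 * log(2) / abs(oracle))
})

test_that("quadrature matches a 2-D Riemann oracle (G family, small prior)", {
  rs <- random_system(6, seed = 83)
  y <- sample_tokens(rs$system, rs$dist, "G", alpha = 25, beta = 1.2,
                     Y = 40, seed = 84)
  sys <- with_counts(rs$system, y)
  pr <- prior_spec(alpha_max = 80)
  lev <- marginal_log_evidence(sys, rs$dist, "G", priors = pr,
                               tol_bytes = 0.01)
  da <- 0.4; db <- 0.01
  agrid <- seq(da / 2, 80 - da / 2, by = da)
  bgrid <- seq(db / 2, 2 - db / 2, by = db)
  total <- 0
  for (a in agrid) {
    A <- drop((1 / (1 + (rs$dist / a)^2)) %*% sys$x)
    for (b in bgrid)
      total <- total + stats::dmultinom(sys$y, prob = naive_probs(sys$x, A, b))
  }
  oracle <- log(total * da * db / (2 * 80)) + log(1 / 4)
  expect_equal(description_length(lev), description_length(oracle),
               tolerance = 0.05 / abs(description_length(oracle)))
})

test_that("evidence never exceeds the MAP likelihood plus prior mass", {
  rs <- random_system(25, seed = 85, clustered = TRUE)
  y <- sample_tokens(rs$system, rs$dist, "E", alpha = 40, beta = 1.3,
                     Y = 2e4, seed = 86)
  sys <- with_counts(rs$system, y)
  for (fam in c("P", "C", "G", "E")) {
    fit <- map_fit(sys, rs$dist, fam, keep_profile = FALSE)
    lev <- marginal_log_evidence(sys, rs$dist, fam)
    expect_lte(as.numeric(lev), fit$loglik + log(1 / 4) + 1e-6)
  }
})

test_that("posterior model probabilities normalise and P pays no Occam tax", {
  rs <- random_system(50, seed = 87, clustered = TRUE)
  y <- sample_tokens(rs$system, rs$dist, "P", Y = 2e4, seed = 88)
  sys <- with_counts(rs$system, y)
  cmp <- compare_models(sys, rs$dist, B = 0)
  expect_equal(sum(cmp$table$post_prob), 1, tolerance = 1e-9)
  expect_identical(cmp$table$delta_D[cmp$table$family == "P"], 0)
  # the extra exponent of the C family is penalised on per-capita data
  expect_gt(cmp$table$D_bytes[cmp$table$family == "C"],
            cmp$table$D_bytes[cmp$table$family == "P"])
})

test_that("city-generated data overwhelmingly rejects per-capita", {
  rs <- random_system(50, seed = 89, clustered = TRUE)
  y <- sample_tokens(rs$system, rs$dist, "C", beta = 1.3, Y = 1e6,
                     seed = 90)
  sys <- with_counts(rs$system, y)
  cmp <- compare_models(sys, rs$dist, B = 0)
  expect_false(cmp$winner == "P")
  dn <- cmp$table$delta_D[cmp$table$family == cmp$winner]
  expect_lt(dn, -100)
  # winner is C itself or a spatial family collapsed onto it
  if (cmp$winner %in% c("G", "E"))
    expect_lt(cmp$table$alpha_hat[cmp$table$family == cmp$winner], 1)
})

test_that("Laplace approximation agrees at interior optima, refuses edges", {
  rs <- random_system(60, seed = 91, clustered = TRUE)
  y <- sample_tokens(rs$system, rs$dist, "G", alpha = 30, beta = 1.25,
                     Y = 1e5, seed = 92)
  sys <- with_counts(rs$system, y)
  for (fam in c("C", "G")) {
    fit <- map_fit(sys, rs$dist, fam, keep_profile = FALSE)
    lap <- laplace_log_evidence(sys, rs$dist, fit)
    lev <- marginal_log_evidence(sys, rs$dist, fam)
    expect_equal(description_length(lap), description_length(lev),
                 tolerance = 1 / abs(description_length(lev)))
  }
  # boundary MAP: all tokens in the most attractive unit drives beta to 2
  A <- attractiveness(rs$system, rs$dist, "C")
  yb <- numeric(60); yb[which.max(A)] <- 1000
  fb <- map_fit(with_counts(rs$system, yb), rs$dist, "C",
                keep_profile = FALSE)
  expect_error(laplace_log_evidence(with_counts(rs$system, yb), rs$dist, fb),
               "refused")
  # alpha MAP at the prior discontinuity alpha = 0
  yc <- sample_tokens(rs$system, rs$dist, "C", beta = 1.3, Y = 1e6,
                      seed = 93)
  sysc <- with_counts(rs$system, yc)
  fg <- map_fit(sysc, rs$dist, "G", keep_profile = FALSE)
  if (fg$alpha_hat <= 0)
    expect_error(laplace_log_evidence(sysc, rs$dist, fg), "refused")
})

test_that("comparison table flags ties the data cannot adjudicate", {
  rs <- random_system(40, seed = 95, clustered = TRUE)
  y <- sample_tokens(rs$system, rs$dist, "G", alpha = 30, beta = 1.2,
                     Y = 1e5, seed = 96)
  sys <- with_counts(rs$system, y)
  cmp <- compare_models(sys, rs$dist, families = c("P", "G", "E"), B = 0,
                        tie_tol_bytes = 1e6)
  expect_true(all(cmp$table$tie))   # absurdly wide tolerance ties everything
  expect_error(compare_models(sys, rs$dist, families = "P"), "at least two")
})
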