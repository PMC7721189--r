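#' Distance-decay interaction kernels
#'
#' Pairwise interaction strength `a(d; alpha)` between two individuals a
#' distance `d` apart, normalised so that `a(0) = 1`. Three families:
#'
#' * `"C"` (city): `a(d) = 1` if `d = 0`, else `0` -- interactions only within
#'   the same unit (same-location units do interact).
#' * `"G"` (gravitational, Lorentzian): `a(d) = 1 / (1 + (d/alpha)^2)`.
#' * `"E"` (exponential): `a(d) = exp(-d * log(2) / alpha)`.
#'
#' For `G` and `E` the range parameter `alpha` is the half-decay scale:
#' `a(alpha; alpha) = 1/2`. `alpha = 0` is resolved exactly as the `C` kernel
#' (the `alpha -> 0+` limit), and `alpha -> Inf` makes all weights 1, which
#' recovers the per-capita (`P`) model downstream.
#'
#' @param d numeric vector or matrix of distances (km), non-negative.
#' @param family one of `"C"`, `"G"`, `"E"`.
#' @param alpha interaction range in km (ignored for `"C"`; must be `>= 0`).
#' @return Weights in `[0, 1]`, same shape as `d`.
#' @examples
#' kernel_value(c(0, 10, 20, 30), "G", alpha = 10)
#' kernel_value(20, "E", alpha = 10)  # two half-decays: 0.25
#' @export
kernel_value <- function(d, family = c("C", "G", "E"), alpha = NULL) {
  family <- match.arg(family)
  if (any(d < 0)) stop("distances must be non-negative")
  if (family != "C") {
    if (is.null(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
      stop("families G and E require a single alpha >= 0")
    if (alpha == 0) family <- "C"   # exact small-range limit
  }
  w <- switch(family,
    C = (d == 0) * 1,
    G = if (is.infinite(alpha)) d * 0 + 1 else 1 / (1 + (d / alpha)^2),
    E = if (is.infinite(alpha)) d * 0 + 1 else exp(-d * log(2) / alpha))
  w
}

#' Attractiveness of an individual in each unit
#'
#' The effective number of interactions available to one individual living in
#' unit `i`: the kernel-weighted sum of all unit populations,
#' `A_i = sum_i' x_i' a(d_ii'; alpha)`, including the own-unit term with
#' `a(0) = 1`. Consequently `A_i >= x_i` always, with equality for the city
#' kernel, and `A_i -> X` (the total population) as `alpha -> Inf`.
#'
#' `A` depends on populations and distances only, never on the counts `y`, so
#' for a fixed `alpha` it is computed once and reused across values of the
#' scaling exponent `beta`.
#'
#' @inheritParams kernel_value
#' @param system a [city_system()].
#' @param dist distance matrix from [distance_matrix()].
#' @return Numeric vector `A` of length `N`.
#' @examples
#' sys <- city_system(c("a", "b"), c(0, 0.09), c(0, 0), c(100, 300))
#' d <- distance_matrix(sys)
#' attractiveness(sys, d, "C")         # equals populations
#' @export
attractiveness <- function(system, dist, family = c("C", "G", "E"),
                           alpha = NULL) {
  family <- match.arg(family)
  validate_distance_matrix(dist, system$N)
  if (family == "C" || (!is.null(alpha) && alpha == 0)) {
    # own unit plus any unit at the exact same location
    return(as.vector((dist == 0) %*% system$x))
  }
  w <- kernel_value(dist, family, alpha)
  as.vector(w %*% system$x)
}

#' Attractiveness relative to own population
#'
#' `A_i / x_i >= 1`: how much spatial interactions inflate the effective
#' interaction pool of an individual beyond their own unit. Equals 1
#' everywhere for the city kernel and is non-decreasing in `alpha`.
#'
#' @inheritParams attractiveness
#' @return Numeric vector of ratios `A/x`, length `N`.
#' @export
attractiveness_ratio <- function(system, dist, family = c("C", "G", "E"),
                                 alpha = NULL) {
  attractiveness(system, dist, family, alpha) / system$x
}

#' Export an attractiveness-ratio table
#'
#' Tidy per-unit table (`unit_id, x, A, ratio`) for plotting interactivity
#' against population.
#'
#' @inheritParams attractiveness
#' @param path optional CSV output path.
#' @return A data frame, invisibly written to `path` when given.
#' @export
attractiveness_table <- function(system, dist, family = c("C", "G", "E"),
                                 alpha = NULL, path = NULL) {
  A <- attractiveness(system, dist, family, alpha)
  out <- data.frame(unit_id = system$unit_id, x = system$x, A = A,
                    ratio = A / system$x)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
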