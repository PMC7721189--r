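#' Conventional log-log straight-line fit
#'
#' Ordinary least squares of `log y` on `log x`, the textbook way of
#' estimating a scaling exponent. Included as the comparison baseline: it
#' weighs every unit equally regardless of size, silently discards units
#' with `y = 0` (they have no logarithm), and defines no generative
#' likelihood, so it cannot enter the description-length comparison.
#'
#' Natural logs are used internally; the slope is base-invariant and the
#' intercept is returned in natural-log units.
#'
#' @param system a [city_system()] with counts.
#' @return A list with `beta` (the slope), `intercept` (natural log),
#'   `n_used` and `n_excluded` (zero-count units dropped).
#' @examples
#' sys <- city_system(letters[1:3], c(0, 1, 2), c(0, 0, 0),
#'                    population = c(10, 100, 1000), count = c(5, 40, 320))
#' loglog_linear_fit(sys)$beta   # log10(8) on equally log-spaced x
#' @export
loglog_linear_fit <- function(system) {
  if (is.null(system$y)) stop("system has no observed counts")
  use <- system$y > 0
  if (sum(use) < 2L)
    stop("fewer than 2 units with positive counts; cannot fit")
  fit <- stats::lm(log(y) ~ log(x),
                   data = data.frame(x = system$x[use], y = system$y[use]))
  co <- stats::coef(fit)
  list(beta = unname(co[2L]), intercept = unname(co[1L]),
       n_used = sum(use), n_excluded = sum(!use))
}
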