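#' Sample a synthetic spatially embedded city system
#'
#' Generates unit centroids and heavy-tailed populations emulating the shape
#' of national municipal data: a continental-scale bounding box, units
#' clustered into metropolitan-like agglomerations (so that small inter-city
#' distances of tens of km, the scales at which people plausibly interact,
#' are well represented), and populations drawn from a Zipf-like (Pareto) or
#' lognormal law. Token counts are added separately with [sample_tokens()].
#'
#' With `n_clusters = 0` the centroids are uniform in the box. Otherwise
#' each unit is attached to one of `n_clusters` uniformly placed cluster
#' centres and jittered by a Gaussian of `cluster_sd_km` km in each
#' direction, then clipped to the box.
#'
#' @param n number of units (`>= 2`).
#' @param pop_law `"zipf"` (Pareto tail, exponent `zipf_s`) or
#'   `"lognormal"`.
#' @param zipf_s Zipf/Pareto size exponent (density `~ x^-s`); 2 is the
#'   classic city-size value.
#' @param pop_min minimum population (Pareto scale parameter).
#' @param meanlog,sdlog lognormal parameters (used when
#'   `pop_law = "lognormal"`).
#' @param bbox named numeric vector `lat_min, lat_max, lon_min, lon_max` in
#'   degrees; the default spans roughly a continent.
#' @param n_clusters number of metropolitan-like clusters (0 = uniform).
#' @param cluster_sd_km within-cluster centroid spread in km.
#' @param seed integer seed; fully determines the output.
#' @return A [city_system()] without counts.
#' @export
sample_city_system <- function(n,
                               pop_law = c("zipf", "lognormal"),
                               zipf_s = 2, pop_min = 1000,
                               meanlog = 9, sdlog = 1.2,
                               bbox = c(lat_min = -33, lat_max = 5,
                                        lon_min = -73, lon_max = -35),
                               n_clusters = 25, cluster_sd_km = 40,
                               seed = NULL) {
  pop_law <- match.arg(pop_law)
  if (n < 2L) stop("need at least 2 units")
  stopifnot(all(c("lat_min", "lat_max", "lon_min", "lon_max") %in%
                  names(bbox)),
            bbox["lat_min"] < bbox["lat_max"],
            bbox["lon_min"] < bbox["lon_max"])
  with_seed(seed, {
    if (n_clusters > 0) {
      centres_lat <- stats::runif(n_clusters, bbox["lat_min"], bbox["lat_max"])
      centres_lon <- stats::runif(n_clusters, bbox["lon_min"], bbox["lon_max"])
      k <- sample.int(n_clusters, n, replace = TRUE)
      km_per_deg_lat <- pi * 6371 / 180
      lat <- centres_lat[k] +
        stats::rnorm(n, sd = cluster_sd_km) / km_per_deg_lat
      lon <- centres_lon[k] +
        stats::rnorm(n, sd = cluster_sd_km) /
        (km_per_deg_lat * pmax(cos(centres_lat[k] * pi / 180), 0.1))
      lat <- pmin(pmax(lat, bbox["lat_min"]), bbox["lat_max"])
      lon <- pmin(pmax(lon, bbox["lon_min"]), bbox["lon_max"])
    } else {
      lat <- stats::runif(n, bbox["lat_min"], bbox["lat_max"])
      lon <- stats::runif(n, bbox["lon_min"], bbox["lon_max"])
    }
    x <- switch(pop_law,
      zipf = ceiling(pop_min * stats::runif(n)^(-1 / (zipf_s - 1))),
      lognormal = ceiling(stats::rlnorm(n, meanlog, sdlog)))
    x <- pmax(x, 1)
    city_system(sprintf("u%04d", seq_len(n)), lat, lon, x)
  })
}

#' Draw token counts from a generative model
#'
#' One multinomial draw of `Y` tokens over the units with the allocation
#' probabilities of the chosen family and parameters. Sampling at city level
#' is exact under the model: individuals within a unit are exchangeable, so
#' the per-person allocation aggregates to a single multinomial over units.
#'
#' @param system a [city_system()] (counts, if present, are ignored).
#' @param dist distance matrix (km); may be `NULL` for families `P`/`C`.
#' @param family one of `"P"`, `"C"`, `"G"`, `"E"`.
#' @param alpha interaction range (families G/E).
#' @param beta scaling exponent (ignored for P, which fixes it at 1).
#' @param Y total token count (positive integer).
#' @param seed integer seed.
#' @return Integer vector `y` of length `N` with `sum(y) = Y`.
#' @export
sample_tokens <- function(system, dist = NULL,
                          family = c("P", "C", "G", "E"),
                          alpha = NULL, beta = 1, Y, seed = NULL) {
  family <- match.arg(family)
  if (Y < 1) stop("Y must be at least 1")
  if (abs(Y - round(Y)) > 0) stop("Y must be an integer token total")
  A <- switch(family,
              P = system$x,
              C = if (is.null(dist)) system$x
                  else attractiveness(system, dist, "C"),
              attractiveness(system, dist, family, alpha))
  if (family == "P") beta <- 1
  p <- city_token_probabilities(system$x, A, beta)
  with_seed(seed, as.vector(stats::rmultinom(1L, size = Y, prob = p)))
}

#' Attach counts to a city system
#'
#' @param system a [city_system()].
#' @param y non-negative count vector of length `N`.
#' @return The system with `y` (and `Y`) set.
#' @export
with_counts <- function(system, y) {
  city_system(system$unit_id, system$lat, system$lon, system$x, count = y)
}
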