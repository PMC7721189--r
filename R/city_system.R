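#' Construct a city system
#'
#' A `city_system` holds the spatial units of a scaling-law analysis: an
#' identifier, centroid coordinates (decimal degrees), the population `x` of
#' each unit and, optionally, the observed token count `y` (GDP units, deaths,
#' road miles, ...). Totals `X = sum(x)` and `Y = sum(y)` and the unit count
#' `N` are carried along.
#'
#' Counts need not be integers: continuous observables such as GDP are
#' accepted and handled through the log-gamma extension of the multinomial
#' coefficient (see [log_likelihood()]).
#'
#' @param unit_id character vector of unit labels (must be unique).
#' @param lat,lon numeric centroid coordinates in decimal degrees;
#'   `lat` in \[-90, 90\], `lon` in \[-180, 180\].
#' @param population numeric vector of strictly positive populations.
#' @param count optional numeric vector of non-negative observed counts.
#'
#' @return An object of class `city_system`: a list with elements `unit_id`,
#'   `lat`, `lon`, `x`, `y` (or `NULL`), `N`, `X`, `Y`.
#' @seealso [read_city_system()], [distance_matrix()]
#' @examples
#' sys <- city_system(c("a", "b"), lat = c(0, 0.1), lon = c(0, 0),
#'                    population = c(100, 300), count = c(10, 50))
#' sys$X
#' @export
city_system <- function(unit_id, lat, lon, population, count = NULL) {
  unit_id <- as.character(unit_id)
  n <- length(unit_id)
  if (n < 2L)
    stop("a city system needs at least 2 units (the scaling exponent is ",
         "unidentifiable with a single unit)")
  if (anyDuplicated(unit_id))
    stop("duplicated unit_id: ",
         paste(unique(unit_id[duplicated(unit_id)]), collapse = ", "))
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  population <- as.numeric(population)
  stopifnot(length(lat) == n, length(lon) == n, length(population) == n)
  bad <- which(!is.finite(lat) | lat < -90 | lat > 90 |
               !is.finite(lon) | lon < -180 | lon > 180)
  if (length(bad))
    stop("coordinates out of range for unit(s): ",
         paste(unit_id[bad], collapse = ", "))
  if (any(!is.finite(population) | population <= 0))
    stop("populations must be positive and finite; offending unit(s): ",
         paste(unit_id[!is.finite(population) | population <= 0],
               collapse = ", "))
  if (!is.null(count)) {
    count <- as.numeric(count)
    stopifnot(length(count) == n)
    if (any(!is.finite(count) | count < 0))
      stop("counts must be non-negative and finite; offending unit(s): ",
           paste(unit_id[!is.finite(count) | count < 0], collapse = ", "))
  }
  structure(
    list(unit_id = unit_id, lat = lat, lon = lon,
         x = population, y = count,
         N = n, X = sum(population),
         Y = if (is.null(count)) NA_real_ else sum(count)),
    class = "city_system")
}

#' @export
print.city_system <- function(x, ...) {
  cat("<city_system> ", x$N, " units, total population ",
      format(x$X, big.mark = ","), sep = "")
  if (!is.null(x$y))
    cat(", total count ", format(x$Y, big.mark = ","), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
format.city_system <- function(x, ...) {
  sprintf("<city_system: N=%d, X=%g, Y=%s>", x$N, x$X,
          if (is.null(x$y)) "NA" else format(x$Y))
}

#' @export
as.data.frame.city_system <- function(x, ...) {
  d <- data.frame(unit_id = x$unit_id, lat = x$lat, lon = x$lon,
                  population = x$x, stringsAsFactors = FALSE)
  if (!is.null(x$y)) d$count <- x$y
  d
}

#' Read a city system from CSV
#'
#' Expects a header with columns `unit_id, lat, lon, population, count`
#' (`count` may be absent when only simulation is intended). Units with zero
#' population are dropped with a warning -- `log(x)` enters the likelihood, so
#' such units carry no usable information under the model.
#'
#' @param path path to a CSV file.
#' @return A [city_system()].
#' @export
read_city_system <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "lat", "lon", "population")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("input CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  zero <- which(!is.na(d$population) & d$population == 0)
  if (length(zero)) {
    warning("dropping ", length(zero),
            " unit(s) with zero population: ",
            paste(utils::head(d$unit_id[zero], 5L), collapse = ", "),
            if (length(zero) > 5L) ", ..." else "")
    d <- d[-zero, , drop = FALSE]
  }
  city_system(d$unit_id, d$lat, d$lon, d$population,
              count = if ("count" %in% names(d)) d$count else NULL)
}

#' Write a city system to CSV
#'
#' Writes the schema read by [read_city_system()].
#'
#' @param system a [city_system()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_city_system <- function(system, path) {
  utils::write.csv(as.data.frame(system), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Great-circle distance matrix between unit centroids
#'
#' Haversine distances on a sphere, in kilometres. The default radius is the
#' Earth radius 6371 km, which is also the default upper prior bound for the
#' interaction range `alpha`.
#'
#' @param system a [city_system()].
#' @param radius_km sphere radius in km (default 6371).
#' @return A symmetric `N x N` numeric matrix of distances in km with zero
#'   diagonal; dimnames are the unit ids.
#' @export
distance_matrix <- function(system, radius_km = 6371) {
  stopifnot(inherits(system, "city_system"), radius_km > 0)
  pts <- cbind(system$lon, system$lat)
  d <- geosphere::distm(pts, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = radius_km * 1000)) / 1000
  # distm is symmetric up to floating point; enforce exactly
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(system$unit_id, system$unit_id)
  d
}

#' Read a user-supplied distance matrix from CSV
#'
#' Supports distances that are not geodesic (e.g. commuting times expressed in
#' km-equivalents). The CSV must be square, with unit ids as both the first
#' column and the header, covering every unit of `system`; rows/columns are
#' reordered to match the system.
#'
#' @param path path to a square CSV keyed by unit_id.
#' @param system the [city_system()] the matrix must cover.
#' @return A symmetric `N x N` matrix in km.
#' @export
read_distance_matrix <- function(path, system) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  d <- as.matrix(d)
  miss <- setdiff(system$unit_id, rownames(d))
  if (length(miss))
    stop("distance matrix is missing unit(s): ", paste(miss, collapse = ", "))
  d <- d[system$unit_id, system$unit_id, drop = FALSE]
  validate_distance_matrix(d, system$N)
  d
}

validate_distance_matrix <- function(d, n) {
  stopifnot(is.matrix(d), nrow(d) == n, ncol(d) == n)
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(abs(d - t(d)) > 1e-8 * (1 + max(d))))
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  invisible(d)
}
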