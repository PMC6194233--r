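#' Mean Earth radius in kilometres (IUGG mean radius).
#' @keywords internal
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between coordinate pairs
#'
#' Spherical law-of-cosines distance,
#' \deqn{d = R \cdot \arccos(\sin\phi_1 \sin\phi_2 +
#'   \cos\phi_1 \cos\phi_2 \cos(\lambda_1 - \lambda_2)),}
#' with latitudes/longitudes in decimal degrees converted to radians and the
#' arccos argument clamped to \[-1, 1\] to guard floating-point rounding for
#' near-identical points. No map projection is ever involved; the model treats
#' the Earth as a sphere of radius `earth_radius_km`.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised,
#'   recycled to a common length).
#' @param earth_radius_km Sphere radius in km. The default is the mean Earth
#'   radius 6371.0088 km.
#' @return Distances in km, in `[0, pi * earth_radius_km]`.
#' @examples
#' great_circle_km(55.7558, 37.6173, 59.9343, 30.3351) # Moscow -> St Petersburg
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2,
                            earth_radius_km = EARTH_RADIUS_KM) {
  stopifnot(is.numeric(earth_radius_km), length(earth_radius_km) == 1,
            earth_radius_km > 0)
  for (nm in c("lat1", "lat2")) {
    v <- get(nm)
    if (anyNA(v) || any(v < -90 | v > 90)) {
      stop("invalid value in '", nm, "': latitude must be in [-90, 90]",
           call. = FALSE)
    }
  }
  for (nm in c("lon1", "lon2")) {
    v <- get(nm)
    if (anyNA(v) || any(v <= -180 | v > 180)) {
      stop("invalid value in '", nm, "': longitude must be in (-180, 180]",
           call. = FALSE)
    }
  }
  rad <- pi / 180
  cosang <- sin(lat1 * rad) * sin(lat2 * rad) +
    cos(lat1 * rad) * cos(lat2 * rad) * cos((lon1 - lon2) * rad)
  earth_radius_km * acos(pmin(1, pmax(-1, cosang)))
}

#' Pairwise great-circle distance matrix over a location table
#'
#' @param locations A location table (see [validate_locations()]).
#' @inheritParams great_circle_km
#' @return A symmetric `n x n` numeric matrix of distances in km with zero
#'   diagonal; row and column names are the location ids in input order.
#' @examples
#' D <- distance_matrix(demo_cities())
#' D["moscow", "yaroslavl"]
#' @export
distance_matrix <- function(locations, earth_radius_km = EARTH_RADIUS_KM) {
  locations <- validate_locations(locations)
  if (nrow(locations) < 2) {
    stop("need at least 2 locations to build a distance matrix", call. = FALSE)
  }
  n <- nrow(locations)
  rad <- pi / 180
  lat <- locations$lat * rad
  lon <- locations$lon * rad
  sl <- sin(lat); cl <- cos(lat)
  # outer() on the spherical law of cosines; clamp guards rounding at ~0 angle
  cosang <- outer(sl, sl) + outer(cl, cl) * cos(outer(lon, lon, "-"))
  D <- earth_radius_km * acos(pmin(pmax(cosang, -1), 1))
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(locations$id, locations$id)
  D
}

#' Long-format view of a distance matrix
#'
#' Upper-triangle pairs only, suitable for CSV export and for comparison with
#' published pairwise-distance tables.
#'
#' @param D A distance matrix from [distance_matrix()].
#' @return A tibble with columns `id_i`, `id_j`, `distance_km`.
#' @export
distance_table <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), !is.null(rownames(D)))
  ids <- rownames(D)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  tibble::tibble(
    id_i = ids[idx[, "row"]],
    id_j = ids[idx[, "col"]],
    distance_km = D[idx]
  )
}

#' @rdname distance_table
#' @param path Output CSV path (`id_i,id_j,distance_km`).
#' @export
write_distance_table <- function(D, path) {
  readr::write_csv(distance_table(D), path, progress = FALSE)
  invisible(path)
}
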