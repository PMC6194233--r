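#' Validate a table of locations
#'
#' A location table describes the cities and transport hubs that make up the
#' dispersal network: one row per site with a unique `id`, free-text `name`,
#' `country` and `region` labels (used for regional risk summaries), and WGS84
#' coordinates in decimal degrees.
#'
#' @param locations A data frame with columns `id`, `name`, `country`,
#'   `region`, `lat`, `lon`.
#' @return The input as a tibble, invisibly unchanged apart from class, after
#'   validation. Errors name the offending column; duplicate coordinates
#'   between distinct sites raise a warning (a zero distance is allowed but
#'   worth knowing about).
#' @examples
#' validate_locations(demo_cities())
#' @export
validate_locations <- function(locations) {
  locations <- tibble::as_tibble(locations)
  required <- c("id", "name", "country", "region", "lat", "lon")
  missing <- setdiff(required, names(locations))
  if (length(missing) > 0) {
    stop("location table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(locations) == 0) {
    stop("location table has no rows", call. = FALSE)
  }
  ids <- as.character(locations$id)
  if (anyNA(ids) || any(ids == "")) {
    stop("invalid value in column 'id': ids must be non-missing, non-empty",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate location id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  lat <- locations$lat
  lon <- locations$lon
  if (!is.numeric(lat) || anyNA(lat) || any(lat < -90 | lat > 90)) {
    stop("invalid value in column 'lat': latitudes must be numeric in [-90, 90]",
         call. = FALSE)
  }
  if (!is.numeric(lon) || anyNA(lon) || any(lon <= -180 | lon > 180)) {
    stop("invalid value in column 'lon': longitudes must be numeric in (-180, 180]",
         call. = FALSE)
  }
  coord_key <- paste(lat, lon)
  if (anyDuplicated(coord_key)) {
    warning("distinct locations share identical coordinates; ",
            "their pairwise distance will be 0", call. = FALSE)
  }
  locations$id <- ids
  locations
}

#' Read and write location tables
#'
#' The on-disk dialect is a UTF-8 CSV with header
#' `id,name,country,region,lat,lon`, decimal-point coordinates, one row per
#' location. `write_locations()` round-trips with `read_locations()`.
#'
#' @param path Path to a CSV file.
#' @return `read_locations()` returns a validated tibble of locations.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write_locations(demo_cities(), tmp)
#' read_locations(tmp)
#' @export
read_locations <- function(path) {
  if (!file.exists(path)) stop("location file not found: ", path, call. = FALSE)
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      name = readr::col_character(),
      country = readr::col_character(),
      region = readr::col_character(),
      lat = readr::col_double(),
      lon = readr::col_double()
    ),
    progress = FALSE
  )
  validate_locations(tab)
}

#' @rdname read_locations
#' @param locations A location table (see [validate_locations()]).
#' @export
write_locations <- function(locations, path) {
  locations <- validate_locations(locations)
  readr::write_csv(locations[, c("id", "name", "country", "region", "lat", "lon")],
                   path, progress = FALSE)
  invisible(path)
}
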