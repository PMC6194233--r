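#' Probability-band scheme for risk maps
#'
#' Risk maps render per-city detection probabilities in four bands defined by
#' three cut points (defaults 15, 40 and 85 percent): `<15`, `15-40`,
#' `40-85`, `>85`. A value exactly on a cut point belongs to the band whose
#' label starts at that cut (15.0% falls in `15-40`).
#'
#' @param cuts Strictly increasing cut points in percent, inside (0, 100).
#' @return A `band_scheme` object with the cuts and the derived band labels.
#' @export
band_scheme <- function(cuts = c(15, 40, 85)) {
  if (length(cuts) < 1 || anyNA(cuts) || any(cuts <= 0 | cuts >= 100) ||
      is.unsorted(cuts, strictly = TRUE)) {
    stop("band cut points must be strictly increasing and inside (0, 100)",
         call. = FALSE)
  }
  labels <- c(
    paste0("<", cuts[1]),
    if (length(cuts) > 1)
      paste0(cuts[-length(cuts)], "-", cuts[-1]),
    paste0(">", cuts[length(cuts)])
  )
  structure(list(cuts = cuts, labels = labels), class = "band_scheme")
}

#' Classify probabilities into risk bands
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param scheme A [band_scheme()].
#' @return A factor with one level per band, lowest first.
#' @examples
#' classify_bands(c(0.10, 0.15, 0.50, 0.99))
#' @export
classify_bands <- function(probabilities, scheme = band_scheme()) {
  stopifnot(inherits(scheme, "band_scheme"))
  if (anyNA(probabilities) || any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  cut(100 * probabilities,
      breaks = c(-Inf, scheme$cuts, Inf),
      labels = scheme$labels,
      right = FALSE)
}

#' Band membership table for one year of a trajectory
#'
#' @param trajectory A `spread_trajectory`.
#' @param year Year to classify.
#' @param scheme A [band_scheme()].
#' @return A tibble with one row per location: `id`, `name`, `country`,
#'   `region`, `probability`, `percent`, `band`.
#' @export
band_table <- function(trajectory, year, scheme = band_scheme()) {
  p <- probabilities_at(trajectory, year)
  loc <- trajectory$locations
  tibble::tibble(
    id = loc$id,
    name = loc$name,
    country = loc$country,
    region = loc$region,
    probability = unname(p[loc$id]),
    percent = round_half_up(100 * unname(p[loc$id])),
    band = classify_bands(unname(p[loc$id]), scheme)
  )
}

#' Verify a model against survey outcomes
#'
#' Cross-tabulates the model's probability bands at `year` against binary
#' survey labels (positives: any detection up to `year`; negatives: surveyed
#' but never positive). Alongside the contingency counts it reports the two
#' quantities that discriminate kernels in practice: the largest model
#' probability at any negative-survey location (a well-behaved model keeps
#' this moderate) and the range of model probabilities at *remote* positive
#' locations — detections farther than `remote_km` from the seed, which thin-
#' tailed kernels cannot reach.
#'
#' @param trajectory A `spread_trajectory`.
#' @param surveys A survey table (see [validate_surveys()]).
#' @param year Year of the trajectory to verify (default: last year).
#' @param scheme A [band_scheme()].
#' @param seed_ids Seed id(s) used for the remote-distance summary; default
#'   taken as the locations with probability 1 in the trajectory's first year.
#' @param remote_km Distance threshold (km) defining "remote" positives.
#' @param earth_radius_km Sphere radius for seed distances.
#' @return A `spread_verification` object: `$counts` (tibble band x outcome),
#'   `$max_negative_probability`, `$remote_positive_range` (named min/max,
#'   `NA` if no remote positive exists), `$n_positive`, `$n_negative`.
#' @export
verification_table <- function(trajectory, surveys,
                               year = max(trajectory$years),
                               scheme = band_scheme(),
                               seed_ids = NULL, remote_km = 200,
                               earth_radius_km = EARTH_RADIUS_KM) {
  p <- probabilities_at(trajectory, year)
  surveys <- validate_surveys(surveys)
  unknown <- setdiff(surveys$location_id, names(p))
  if (length(unknown) > 0) {
    stop("surveyed location(s) missing from the network: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  labels <- build_labels(surveys, year)
  if (nrow(labels) == 0) {
    counts <- tibble::tibble(band = factor(scheme$labels, levels = scheme$labels),
                             detected = 0L, not_detected = 0L)
    return(structure(list(counts = counts, max_negative_probability = NA_real_,
                          remote_positive_range = c(min = NA_real_, max = NA_real_),
                          n_positive = 0L, n_negative = 0L, year = year),
                     class = "spread_verification"))
  }
  labels$probability <- unname(p[labels$location_id])
  labels$band <- classify_bands(labels$probability, scheme)
  labels$outcome <- ifelse(labels$label == 1, "detected", "not_detected")
  counts <- labels |>
    dplyr::count(.data$band, .data$outcome, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "n",
                       values_fill = 0L)
  for (col in c("detected", "not_detected")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts <- counts[, c("band", "detected", "not_detected")]

  loc <- trajectory$locations
  if (is.null(seed_ids)) {
    first <- trajectory$P[, 1]
    seed_ids <- names(first)[first >= 1]
  }
  seed_rows <- loc[loc$id %in% seed_ids, , drop = FALSE]
  dist_to_seed <- rep(Inf, nrow(loc))
  for (s in seq_len(nrow(seed_rows))) {
    dist_to_seed <- pmin(dist_to_seed,
                         great_circle_km(loc$lat, loc$lon,
                                         seed_rows$lat[s], seed_rows$lon[s],
                                         earth_radius_km))
  }
  names(dist_to_seed) <- loc$id
  neg_p <- labels$probability[labels$label == 0]
  pos <- labels[labels$label == 1, , drop = FALSE]
  remote <- pos[dist_to_seed[pos$location_id] > remote_km, , drop = FALSE]
  remote_range <- if (nrow(remote) > 0) {
    c(min = min(remote$probability), max = max(remote$probability))
  } else {
    c(min = NA_real_, max = NA_real_)
  }
  structure(
    list(
      counts = counts,
      max_negative_probability = if (length(neg_p) > 0) max(neg_p) else NA_real_,
      remote_positive_range = remote_range,
      n_positive = sum(labels$label == 1),
      n_negative = sum(labels$label == 0),
      year = year
    ),
    class = "spread_verification"
  )
}

#' @export
print.spread_verification <- function(x, ...) {
  cat(sprintf("<spread_verification> year %d: %d positive, %d negative surveys\n",
              x$year, x$n_positive, x$n_negative))
  print(as.data.frame(x$counts), row.names = FALSE)
  if (!is.na(x$max_negative_probability)) {
    cat(sprintf("  max probability at negative locations: %.3f\n",
                x$max_negative_probability))
  }
  if (!is.na(x$remote_positive_range["min"])) {
    cat(sprintf("  remote positives: probability %.3f-%.3f\n",
                x$remote_positive_range["min"], x$remote_positive_range["max"]))
  }
  invisible(x)
}

#' Maximum detection probability per country or region
#'
#' The headline numbers for cross-border risk: for each administrative group,
#' the largest modelled detection probability among its cities in a given
#' year.
#'
#' @param trajectory A `spread_trajectory`.
#' @param year Year to summarise.
#' @param group Grouping column of the location table, unquoted (`country` or
#'   `region`).
#' @return A tibble with the group column, `max_probability` (full
#'   precision) and `percent` (whole percent, round half up), sorted
#'   decreasing.
#' @examples
#' traj <- simulate_spread(demo_cities(), dispersal_kernel("cauchy", 10.125),
#'                         "moscow", 2003, 2017)
#' regional_max(traj, 2017, region)
#' @export
regional_max <- function(trajectory, year, group) {
  p <- probabilities_at(trajectory, year)
  loc <- trajectory$locations
  loc$probability <- unname(p[loc$id])
  loc |>
    dplyr::group_by({{ group }}) |>
    dplyr::summarise(max_probability = max(.data$probability),
                     .groups = "drop") |>
    dplyr::mutate(percent = round_half_up(100 * .data$max_probability)) |>
    dplyr::arrange(dplyr::desc(.data$max_probability))
}

#' Export one year of a trajectory as GeoJSON
#'
#' Writes an RFC 7946 FeatureCollection with one Point feature per location
#' (coordinates in `[lon, lat]` order) and properties `name`, `country`,
#' `region`, `probability`, `band`, `year` — ready for any web map.
#'
#' @param trajectory A `spread_trajectory`.
#' @param year Year to export.
#' @param path Output `.geojson` path.
#' @param scheme A [band_scheme()].
#' @return The path, invisibly.
#' @export
export_geojson <- function(trajectory, year, path, scheme = band_scheme()) {
  tab <- band_table(trajectory, year, scheme)
  loc <- trajectory$locations
  features <- purrr::pmap(
    list(loc$lon, loc$lat, tab$name, tab$country, tab$region,
         tab$probability, as.character(tab$band)),
    function(lon, lat, name, country, region, probability, band) {
      list(
        type = "Feature",
        geometry = list(type = "Point", coordinates = c(lon, lat)),
        properties = list(name = name, country = country, region = region,
                          probability = probability, band = band,
                          year = as.integer(year))
      )
    }
  )
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
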