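#' Generate a clustered synthetic city network
#'
#' Draws a network of cities with the spatial structure the spread model
#' assumes: transport hubs clustered in space, with one well-defined
#' epicenter. Cluster centres are drawn uniformly in a square bounding box
#' around the epicenter; each city is assigned a random cluster and displaced
#' from its centre by an isotropic Gaussian of scale `cluster_spread_km`.
#' The first city is placed exactly at the epicenter and carries id `"seed"`.
#'
#' Kilometre displacements are converted to degrees on the sphere (longitude
#' scaled by `cos(lat)`), so the generator stays consistent with
#' [distance_matrix()] away from the poles.
#'
#' @param n_cities Number of cities (>= 2), including the epicenter city.
#' @param epicenter Named vector `c(lat = , lon = )` in decimal degrees.
#' @param n_clusters Number of cluster centres.
#' @param cluster_spread_km Gaussian scatter of cities around their centre, km.
#' @param box_half_km Half-width of the bounding box for cluster centres, km.
#'   The default (800 km) matches the extent of the European-Russia city
#'   network the model was developed on (Moscow to the Baltic and Ukrainian
#'   hubs is 600-900 km) and keeps threshold survey labels mixed rather than
#'   saturated after a decade of spread.
#' @param seed RNG seed; the same seed always yields the same network.
#' @return A location tibble (see [validate_locations()]); regions are the
#'   cluster labels, and the epicenter row has `id == "seed"`.
#' @examples
#' net <- generate_city_network(50, seed = 1)
#' @export
generate_city_network <- function(n_cities,
                                  epicenter = c(lat = 55.7558, lon = 37.6173),
                                  n_clusters = 8,
                                  cluster_spread_km = 80,
                                  box_half_km = 800,
                                  seed = 1) {
  if (n_cities < 2) stop("n_cities must be >= 2", call. = FALSE)
  if (cluster_spread_km <= 0) stop("cluster_spread_km must be > 0", call. = FALSE)
  km_per_deg <- EARTH_RADIUS_KM * pi / 180
  withr::with_seed(seed, {
    centre_x <- stats::runif(n_clusters, -box_half_km, box_half_km)
    centre_y <- stats::runif(n_clusters, -box_half_km, box_half_km)
    cluster <- sample.int(n_clusters, n_cities - 1, replace = TRUE)
    x <- centre_x[cluster] + stats::rnorm(n_cities - 1, sd = cluster_spread_km)
    y <- centre_y[cluster] + stats::rnorm(n_cities - 1, sd = cluster_spread_km)
  })
  lat <- pmin(89, pmax(-89, epicenter[["lat"]] + y / km_per_deg))
  lon <- epicenter[["lon"]] + x / (km_per_deg * cos(lat * pi / 180))
  lon <- ((lon + 180) %% 360) - 180
  lon[lon == -180] <- 180
  tibble::tibble(
    id = c("seed", sprintf("city%03d", seq_len(n_cities - 1))),
    name = c("epicenter", sprintf("city %d", seq_len(n_cities - 1))),
    country = "synthetica",
    region = c("cluster0", paste0("cluster", cluster)),
    lat = c(epicenter[["lat"]], lat),
    lon = c(epicenter[["lon"]], lon)
  )
}

#' Simulate survey outcomes on a network under a known kernel
#'
#' The ground-truth generator for parameter-recovery experiments: runs the
#' spread recursion from the seed with a known kernel, then labels every city
#' at `survey_year` either deterministically (`rule = "threshold"`: detected
#' when `P > threshold`) or stochastically (`rule = "bernoulli"`: detected
#' with probability `P`, seeded).
#'
#' @param network A location tibble, e.g. from [generate_city_network()].
#' @param kernel The true [dispersal_kernel()].
#' @param start_year,survey_year Recursion span; labels reflect `survey_year`.
#' @param rule `"threshold"` or `"bernoulli"`.
#' @param threshold Detection threshold for the threshold rule.
#' @param seed RNG seed (used by the Bernoulli rule only).
#' @param seed_ids Epicenter id(s); defaults to `"seed"`.
#' @return A survey tibble (`location_id`, `year`, `outcome`) covering every
#'   city. Warns if all labels come out identical (useless for calibration;
#'   resample or change conditions).
#' @examples
#' net <- generate_city_network(50, seed = 1)
#' simulate_survey_data(net, dispersal_kernel("cauchy", 12), 2003, 2015)
#' @export
simulate_survey_data <- function(network, kernel, start_year, survey_year,
                                 rule = c("threshold", "bernoulli"),
                                 threshold = 0.5, seed = 1,
                                 seed_ids = "seed") {
  rule <- match.arg(rule)
  traj <- simulate_spread(network, kernel, seed_ids, start_year, survey_year)
  p <- probabilities_at(traj, survey_year)
  detected <- if (rule == "threshold") {
    p > threshold
  } else {
    withr::with_seed(seed, stats::runif(length(p)) < p)
  }
  if (all(detected) || all(!detected)) {
    warning("degenerate survey labels (all ",
            if (all(detected)) "positive" else "negative",
            "); calibration needs both classes", call. = FALSE)
  }
  tibble::tibble(
    location_id = names(p),
    year = as.integer(survey_year),
    outcome = unname(ifelse(detected, "detected", "not_detected"))
  )
}

#' A small named demo network of real cities
#'
#' Twenty-one cities of European Russia and neighbouring countries with
#' approximate, public-knowledge coordinates, for examples and smoke tests.
#' This is a synthetic convenience fixture — it is *not* a survey dataset,
#' and the coordinates are rounded city centres.
#'
#' @return A location tibble with Moscow (`id = "moscow"`) as the historical
#'   epicenter of the emerald ash borer invasion.
#' @examples
#' demo_cities()
#' @export
demo_cities <- function() {
  tibble::tribble(
    ~id, ~name, ~country, ~region, ~lat, ~lon,
    "moscow",    "Moscow",          "Russia",    "Moscow",            55.7558, 37.6173,
    "spb",       "Saint Petersburg","Russia",    "Saint Petersburg",  59.9343, 30.3351,
    "yaroslavl", "Yaroslavl",       "Russia",    "Yaroslavl Region",  57.6261, 39.8845,
    "tver",      "Tver",            "Russia",    "Tver Region",       56.8587, 35.9176,
    "kaluga",    "Kaluga",          "Russia",    "Kaluga Region",     54.5293, 36.2754,
    "tula",      "Tula",            "Russia",    "Tula Region",       54.1961, 37.6182,
    "ryazan",    "Ryazan",          "Russia",    "Ryazan Region",     54.6269, 39.6916,
    "vladimir",  "Vladimir",        "Russia",    "Vladimir Region",   56.1366, 40.3966,
    "smolensk",  "Smolensk",        "Russia",    "Smolensk Region",   54.7818, 32.0401,
    "bryansk",   "Bryansk",         "Russia",    "Bryansk Region",    53.2521, 34.3717,
    "orel",      "Orel",            "Russia",    "Orel Region",       52.9685, 36.0697,
    "voronezh",  "Voronezh",        "Russia",    "Voronezh Region",   51.6720, 39.1843,
    "mogilev",   "Mogilev",         "Belarus",   "Mogilev Region",    53.9006, 30.3319,
    "vitebsk",   "Vitebsk",         "Belarus",   "Vitebsk Region",    55.1904, 30.2049,
    "minsk",     "Minsk",           "Belarus",   "Minsk Region",      53.9045, 27.5615,
    "sumy",      "Sumy",            "Ukraine",   "Sumy Region",       50.9077, 34.7981,
    "kharkiv",   "Kharkiv",         "Ukraine",   "Kharkiv Region",    49.9935, 36.2304,
    "kyiv",      "Kyiv",            "Ukraine",   "Kyiv Region",       50.4501, 30.5234,
    "riga",      "Riga",            "Latvia",    "Riga Region",       56.9496, 24.1052,
    "tallinn",   "Tallinn",         "Estonia",   "Harju",             59.4370, 24.7536,
    "vilnius",   "Vilnius",         "Lithuania", "Vilnius Region",    54.6872, 25.2797
  )
}

#' Demo survey records to pair with [demo_cities()]
#'
#' A hand-written, approximate set of detection / non-detection records
#' emulating the broad picture of the emerald ash borer invasion of European
#' Russia: detected in Moscow in 2003, subsequently in surrounding Russian
#' regions, and not (yet) found in the neighbouring countries as of 2016-2017
#' surveys. Synthetic — dates and outcomes are plausible, not sourced.
#'
#' @return A survey tibble (`location_id`, `year`, `outcome`).
#' @export
demo_surveys <- function() {
  tibble::tribble(
    ~location_id, ~year, ~outcome,
    "moscow",    2003L, "detected",
    "tver",      2012L, "detected",
    "kaluga",    2012L, "detected",
    "tula",      2012L, "detected",
    "vladimir",  2012L, "detected",
    "ryazan",    2013L, "detected",
    "yaroslavl", 2013L, "detected",
    "smolensk",  2014L, "detected",
    "orel",      2013L, "detected",
    "voronezh",  2013L, "detected",
    "bryansk",   2015L, "not_detected",
    "spb",       2015L, "not_detected",
    "mogilev",   2015L, "not_detected",
    "vitebsk",   2015L, "not_detected",
    "minsk",     2015L, "not_detected",
    "sumy",      2015L, "not_detected",
    "kharkiv",   2015L, "not_detected",
    "kyiv",      2015L, "not_detected",
    "riga",      2015L, "not_detected",
    "tallinn",   2015L, "not_detected",
    "vilnius",   2015L, "not_detected",
    "bryansk",   2016L, "not_detected",
    "spb",       2017L, "not_detected",
    "mogilev",   2016L, "not_detected",
    "vitebsk",   2016L, "not_detected",
    "minsk",     2017L, "not_detected",
    "sumy",      2016L, "not_detected",
    "kharkiv",   2016L, "not_detected",
    "kyiv",      2017L, "not_detected",
    "riga",      2017L, "not_detected",
    "tallinn",   2017L, "not_detected",
    "vilnius",   2017L, "not_detected"
  )
}
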