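#' One year of the complement-product spread recurrence
#'
#' Advances the per-city detection probability vector by one year:
#' \deqn{P_j(t+1) = 1 - \prod_i \big(1 - P_i(t)\, f(d_{ij})\big),}
#' the chance that at least one of the independent annual introduction events
#' from every city `i` (including `i = j`; `f(0) = 1` makes an established
#' population absorbing, so probabilities never decrease) succeeds.
#'
#' The product is accumulated as a sum of `log1p(-x)` terms, so that many
#' small complements do not underflow and any certain source
#' (`P_i * f(d_ij) = 1`) forces the complement to exactly zero.
#'
#' @param p Numeric vector of current probabilities in `[0, 1]`, one per city,
#'   aligned with `D` (names, if present, must match `rownames(D)`).
#' @param D Pairwise distance matrix from [distance_matrix()].
#' @param kernel A [dispersal_kernel()].
#' @param method `"log"` (default, log-space accumulation) or `"direct"`
#'   (plain product); both agree to high precision and `"direct"` exists as a
#'   cross-check.
#' @return The next year's probability vector, elementwise `>=` the input.
#' @examples
#' cities <- demo_cities()
#' D <- distance_matrix(cities)
#' p0 <- as.numeric(cities$id == "moscow")
#' annual_step(p0, D, dispersal_kernel("cauchy", 10.125))
#' @export
annual_step <- function(p, D, kernel, method = c("log", "direct")) {
  method <- match.arg(method)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (length(p) != nrow(D)) {
    stop("probability vector length (", length(p),
         ") does not match distance matrix size (", nrow(D), ")", call. = FALSE)
  }
  if (!is.null(names(p)) && !is.null(rownames(D)) &&
      !identical(names(p), rownames(D))) {
    stop("names of probability vector do not match distance matrix ids",
         call. = FALSE)
  }
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  f <- kernel_prob(kernel, D)
  m <- p * f # row i scaled by P_i: m[i, j] = P_i * f(d_ij)
  if (method == "log") {
    out <- 1 - exp(colSums(log1p(-m)))
  } else {
    out <- 1 - apply(1 - m, 2, prod)
  }
  # any certain source forces the complement to exactly 0
  out[colSums(m >= 1) > 0] <- 1
  out <- pmin(1, pmax(0, out))
  names(out) <- names(p) %||% rownames(D)
  out
}

new_spread_trajectory <- function(P, years, locations) {
  structure(
    list(P = P, years = years, locations = locations),
    class = "spread_trajectory"
  )
}

#' Simulate the yearly spread recursion over a city network
#'
#' Initialises the detection probability at 1 for the seed city (or cities)
#' and 0 elsewhere in `start_year`, then applies [annual_step()] once per
#' year up to `end_year`. The result is the full probability trajectory
#' `P_j(year)` for every city.
#'
#' @param locations A location table (see [validate_locations()]).
#' @param kernel A [dispersal_kernel()].
#' @param seed_ids Character ids of the epicenter city/cities (probability 1
#'   from `start_year` on).
#' @param start_year,end_year Inclusive integer year range
#'   (`start_year <= end_year`).
#' @param D Optional precomputed distance matrix (otherwise computed from
#'   `locations`).
#' @param earth_radius_km Sphere radius used when `D` is computed here.
#' @param condition_detections Optional survey table (columns `location_id`,
#'   `year`, `outcome`); when supplied, cities with a recorded detection are
#'   overwritten to probability 1 from their detection year onward *during*
#'   the recursion. The default (`NULL`) is the pure model recursion.
#' @return A `spread_trajectory` object; see [tidy.spread_trajectory()],
#'   [probabilities_at()], [autoplot.spread_trajectory()].
#' @examples
#' traj <- simulate_spread(demo_cities(), dispersal_kernel("cauchy", 10.125),
#'                         seed_ids = "moscow", start_year = 2003,
#'                         end_year = 2017)
#' probabilities_at(traj, 2017)
#' @export
simulate_spread <- function(locations, kernel, seed_ids, start_year, end_year,
                            D = NULL, earth_radius_km = EARTH_RADIUS_KM,
                            condition_detections = NULL) {
  locations <- validate_locations(locations)
  if (start_year > end_year) stop("start_year must be <= end_year", call. = FALSE)
  ids <- locations$id
  unknown <- setdiff(seed_ids, ids)
  if (length(unknown) > 0) {
    stop("unknown seed id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(D)) D <- distance_matrix(locations, earth_radius_km)
  years <- start_year:end_year
  p <- stats::setNames(as.numeric(ids %in% seed_ids), ids)
  detect_year <- NULL
  if (!is.null(condition_detections)) {
    det <- validate_surveys(condition_detections)
    det <- dplyr::filter(det, .data$outcome == "detected")
    detect_year <- tapply(det$year, det$location_id, min)
  }
  overwrite <- function(p, yr) {
    if (is.null(detect_year)) return(p)
    hit <- names(detect_year)[detect_year <= yr]
    p[intersect(hit, ids)] <- 1
    p
  }
  p <- overwrite(p, start_year)
  P <- matrix(NA_real_, nrow = length(ids), ncol = length(years),
              dimnames = list(ids, years))
  P[, 1] <- p
  for (k in seq_along(years)[-1]) {
    p <- overwrite(annual_step(p, D, kernel), years[k])
    P[, k] <- p
  }
  new_spread_trajectory(P, years, locations)
}

#' Forecast forward from a conditioned probability vector
#'
#' Runs the same yearly recurrence as [simulate_spread()], but initialised
#' from an arbitrary probability vector — typically the output of
#' [condition_on_detections()], where confirmed detections have been
#' overwritten to 1 before projecting future spread.
#'
#' @param p0 Named probability vector (names = location ids, aligned with
#'   `locations`).
#' @inheritParams simulate_spread
#' @param from_year,to_year Inclusive year range; `p0` is the state at
#'   `from_year`.
#' @return A `spread_trajectory`.
#' @export
forecast_spread <- function(locations, kernel, p0, from_year, to_year,
                            D = NULL, earth_radius_km = EARTH_RADIUS_KM) {
  locations <- validate_locations(locations)
  if (from_year > to_year) stop("from_year must be <= to_year", call. = FALSE)
  ids <- locations$id
  if (is.null(names(p0)) || !setequal(names(p0), ids)) {
    stop("'p0' must be a named vector covering every location id", call. = FALSE)
  }
  p0 <- p0[ids]
  if (anyNA(p0) || any(p0 < 0 | p0 > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(D)) D <- distance_matrix(locations, earth_radius_km)
  years <- from_year:to_year
  P <- matrix(NA_real_, nrow = length(ids), ncol = length(years),
              dimnames = list(ids, years))
  P[, 1] <- p0
  p <- p0
  for (k in seq_along(years)[-1]) {
    p <- annual_step(p, D, kernel)
    P[, k] <- p
  }
  new_spread_trajectory(P, years, locations)
}

#' Overwrite model probabilities with confirmed detections
#'
#' Returns the probability vector of a trajectory at `at_year` with every
#' detected location set to 1 — the conditioning step applied before
#' forecasting, reflecting that an established population is assumed not to
#' disappear.
#'
#' @param trajectory A `spread_trajectory`.
#' @param detections Either a character vector of detected location ids, or a
#'   survey table (columns `location_id`, `year`, `outcome`) from which
#'   detections up to `at_year` are taken.
#' @param at_year Year within the trajectory span.
#' @return A named probability vector.
#' @export
condition_on_detections <- function(trajectory, detections, at_year) {
  p <- probabilities_at(trajectory, at_year)
  if (is.data.frame(detections)) {
    det <- validate_surveys(detections)
    detections <- unique(det$location_id[det$outcome == "detected" &
                                           det$year <= at_year])
  }
  unknown <- setdiff(detections, names(p))
  if (length(unknown) > 0) {
    stop("unknown detection id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[detections] <- 1
  p
}

#' Extract the probability vector at one year
#'
#' @param trajectory A `spread_trajectory`.
#' @param year A year inside the trajectory span.
#' @return Named numeric vector of probabilities.
#' @export
probabilities_at <- function(trajectory, year) {
  stopifnot(inherits(trajectory, "spread_trajectory"))
  if (!year %in% trajectory$years) {
    stop("year ", year, " is outside the trajectory span [",
         min(trajectory$years), ", ", max(trajectory$years), "]", call. = FALSE)
  }
  trajectory$P[, as.character(year)]
}

#' @export
print.spread_trajectory <- function(x, ...) {
  cat(sprintf("<spread_trajectory> %d locations, years %d-%d\n",
              nrow(x$P), min(x$years), max(x$years)))
  final <- x$P[, ncol(x$P)]
  cat(sprintf("  P(%d): min %.4f, median %.4f, max %.4f\n",
              max(x$years), min(final), stats::median(final), max(final)))
  invisible(x)
}

#' Tidy a spread trajectory into a long tibble
#'
#' @param x A `spread_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `year`, `probability` (full double
#'   precision) and `percent` (whole percent, round half up — the
#'   presentation scale used in reports).
#' @method tidy spread_trajectory
#' @export
tidy.spread_trajectory <- function(x, ...) {
  out <- tibble::as_tibble(x$P, rownames = "id")
  out <- tidyr::pivot_longer(out, -"id", names_to = "year",
                             values_to = "probability")
  out$year <- as.integer(out$year)
  out$percent <- round_half_up(100 * out$probability)
  dplyr::arrange(out, .data$year, .data$id)
}

#' @method as_tibble spread_trajectory
#' @export
as_tibble.spread_trajectory <- function(x, ...) tidy.spread_trajectory(x, ...)

#' Write a trajectory to long CSV
#'
#' Columns `id,year,probability,percent`: probabilities at full double
#' precision, plus the rounded-percent presentation column.
#'
#' @param trajectory A `spread_trajectory`.
#' @param path Output CSV path.
#' @export
write_trajectory <- function(trajectory, path) {
  readr::write_csv(tidy(trajectory), path, progress = FALSE)
  invisible(path)
}

#' @describeIn simulate_spread Plot per-city probability trajectories.
#' @param object A `spread_trajectory`.
#' @param ... Unused.
#' @method autoplot spread_trajectory
#' @export
autoplot.spread_trajectory <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$probability,
                                   group = .data$id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "year", y = "detection probability")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round half up (2.5 -> 3), unlike base round()'s round-half-even;
# used only at presentation time for whole-percent report columns
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}
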