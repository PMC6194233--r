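#' Validate a survey table
#'
#' A survey table records binary field observations: one row per visit, with
#' `location_id`, integer `year` and `outcome` (`detected` /
#' `not_detected`, case-insensitive).
#'
#' @param surveys A data frame with columns `location_id`, `year`, `outcome`.
#' @return The validated table as a tibble with normalised outcome strings.
#' @export
validate_surveys <- function(surveys) {
  surveys <- tibble::as_tibble(surveys)
  required <- c("location_id", "year", "outcome")
  missing <- setdiff(required, names(surveys))
  if (length(missing) > 0) {
    stop("survey table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  surveys$location_id <- as.character(surveys$location_id)
  surveys$outcome <- tolower(as.character(surveys$outcome))
  bad <- !surveys$outcome %in% c("detected", "not_detected")
  if (any(bad)) {
    stop("invalid outcome value(s): ",
         paste(unique(surveys$outcome[bad]), collapse = ", "),
         " (expected 'detected' or 'not_detected')", call. = FALSE)
  }
  if (!is.numeric(surveys$year) || anyNA(surveys$year)) {
    stop("survey years must be numeric and non-missing", call. = FALSE)
  }
  surveys$year <- as.integer(surveys$year)
  surveys
}

#' Read and write survey tables
#'
#' CSV dialect: header `location_id,year,outcome`, outcome strings
#' `detected` / `not_detected` (case-insensitive on read).
#'
#' @param path Path to a CSV file.
#' @export
read_surveys <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(
      location_id = readr::col_character(),
      year = readr::col_integer(),
      outcome = readr::col_character()
    ),
    progress = FALSE
  )
  validate_surveys(tab)
}

#' @rdname read_surveys
#' @param surveys A survey table.
#' @export
write_surveys <- function(surveys, path) {
  surveys <- validate_surveys(surveys)
  readr::write_csv(surveys[, c("location_id", "year", "outcome")], path,
                   progress = FALSE)
  invisible(path)
}

#' Build binary calibration labels from survey records
#'
#' A location is labelled `1` (positive) if the pest was detected there in any
#' year up to `reference_year`; `0` (negative) if it has at least one negative
#' survey up to `reference_year` and no detection; locations with no usable
#' record are excluded. A detection always overrides negative surveys,
#' including same-year conflicts (which are flagged with a warning).
#'
#' @param surveys A survey table (see [validate_surveys()]).
#' @param reference_year Labels reflect the state of knowledge at the end of
#'   this year.
#' @return A tibble with columns `location_id`, `label` (0/1); the reference
#'   year is stored in the `reference_year` attribute.
#' @examples
#' build_labels(demo_surveys(), 2015)
#' @export
build_labels <- function(surveys, reference_year) {
  surveys <- validate_surveys(surveys)
  upto <- dplyr::filter(surveys, .data$year <= reference_year)
  conflict <- upto |>
    dplyr::distinct(.data$location_id, .data$year, .data$outcome) |>
    dplyr::count(.data$location_id, .data$year) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflict) > 0) {
    warning("conflicting same-year survey records at: ",
            paste(unique(conflict$location_id), collapse = ", "),
            "; detection wins", call. = FALSE)
  }
  labels <- upto |>
    dplyr::group_by(.data$location_id) |>
    dplyr::summarise(label = as.integer(any(.data$outcome == "detected")),
                     .groups = "drop")
  attr(labels, "reference_year") <- as.integer(reference_year)
  labels
}

# recursion on a prebuilt distance matrix; hot path shared by the objective
run_recursion <- function(D, kernel, seed_idx, n_steps) {
  f <- kernel_prob(kernel, D)
  p <- numeric(nrow(D))
  p[seed_idx] <- 1
  for (k in seq_len(n_steps)) {
    m <- p * f
    p <- 1 - exp(colSums(log1p(-m)))
    p[colSums(m >= 1) > 0] <- 1
  }
  stats::setNames(pmin(1, pmax(0, p)), rownames(D))
}

#' Least-squares objective for kernel calibration
#'
#' Runs the spread recursion from the seed city in `start_year` to the
#' reference year of `labels` with the kernel `(family, theta)`, and returns
#' the sum over labelled locations of squared differences between the
#' calculated detection probability and the 0/1 label.
#'
#' @param theta Positive kernel parameter.
#' @param family Kernel family (see [dispersal_kernel()]).
#' @param D Distance matrix with location ids as dimnames.
#' @param labels Label tibble from [build_labels()] (or any tibble with
#'   `location_id`, `label` and a `reference_year` attribute).
#' @param seed_ids Epicenter id(s).
#' @param start_year First year of the recursion.
#' @param reference_year Year at which probabilities are compared to labels;
#'   defaults to the labels' own reference year.
#' @return A single non-negative number.
#' @export
sse_objective <- function(theta, family, D, labels, seed_ids, start_year,
                          reference_year = attr(labels, "reference_year")) {
  if (is.null(reference_year)) {
    stop("no reference year: pass 'reference_year' or labels from build_labels()",
         call. = FALSE)
  }
  if (reference_year < start_year) {
    stop("reference_year must be >= start_year", call. = FALSE)
  }
  ids <- rownames(D)
  missing <- setdiff(labels$location_id, ids)
  if (length(missing) > 0) {
    stop("labelled location(s) missing from the network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  seed_idx <- match(seed_ids, ids)
  if (anyNA(seed_idx)) {
    stop("unknown seed id(s): ",
         paste(seed_ids[is.na(seed_idx)], collapse = ", "), call. = FALSE)
  }
  kernel <- dispersal_kernel(family, theta)
  p <- run_recursion(D, kernel, seed_idx, reference_year - start_year)
  sum((p[labels$location_id] - labels$label)^2)
}

#' Fit a kernel parameter by least squares
#'
#' Minimises [sse_objective()] over `theta`: a log-spaced grid scan over the
#' search bounds locates the basin, then the bracketing interval around the
#' best grid point is refined with one-dimensional minimisation
#' ([stats::optimize()], golden-section search with parabolic interpolation)
#' to relative tolerance `tol`. A fit whose optimum sits at a search bound is
#' flagged (`boundary = TRUE`) and warned about rather than silently
#' accepted.
#'
#' @param locations A location table; the distance matrix is computed from it
#'   unless `D` is supplied.
#' @param surveys A survey table; labels at `reference_year` are built from
#'   it via [build_labels()] unless `labels` is supplied.
#' @inheritParams sse_objective
#' @param D Optional precomputed distance matrix.
#' @param labels Optional prebuilt label tibble.
#' @param lower,upper Search bounds for `theta`.
#' @param n_grid Number of log-spaced grid points scanned before refinement.
#' @param tol Relative tolerance of the refinement stage.
#' @param earth_radius_km Sphere radius used when `D` is computed here.
#' @return An object of class `kernel_fit`: the fitted [dispersal_kernel()],
#'   the minimised sum of squares, label counts, the scanned objective curve
#'   and the boundary flag. Supports [tidy()], [glance()] and `autoplot()`.
#' @examples
#' fit <- fit_kernel(demo_cities(), demo_surveys(), family = "cauchy",
#'                   seed_ids = "moscow", start_year = 2003,
#'                   reference_year = 2015)
#' glance(fit)
#' @export
fit_kernel <- function(locations, surveys,
                       family = c("exponential", "normal", "cauchy"),
                       seed_ids, start_year, reference_year,
                       D = NULL, labels = NULL,
                       lower = 1e-6, upper = 1e3, n_grid = 200, tol = 1e-6,
                       earth_radius_km = EARTH_RADIUS_KM) {
  family <- match.arg(family)
  if (is.null(D)) {
    locations <- validate_locations(locations)
    D <- distance_matrix(locations, earth_radius_km)
  }
  if (is.null(labels)) labels <- build_labels(surveys, reference_year)
  n_pos <- sum(labels$label == 1)
  n_neg <- sum(labels$label == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("degenerate label set; objective unbounded toward a trivial kernel ",
         "(need at least one positive and one negative label)", call. = FALSE)
  }
  obj <- function(theta) {
    sse_objective(theta, family, D, labels, seed_ids, start_year, reference_year)
  }
  grid <- exp(seq(log(lower), log(upper), length.out = n_grid))
  sse_grid <- vapply(grid, obj, numeric(1))
  if (any(!is.finite(sse_grid))) {
    stop("objective is not finite over the search grid", call. = FALSE)
  }
  i <- which.min(sse_grid)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(n_grid, i + 1)]
  ref <- stats::optimize(obj, c(lo, hi), tol = max(tol * grid[i], 1e-12))
  theta_hat <- ref$minimum
  sse_hat <- ref$objective
  if (sse_grid[i] < sse_hat) { # grid point can beat the refinement at a bound
    theta_hat <- grid[i]
    sse_hat <- sse_grid[i]
  }
  boundary <- i == 1 || i == n_grid
  if (boundary) {
    warning("fitted theta is at the edge of the search bounds [",
            format(lower), ", ", format(upper), "]; treat the fit with caution",
            call. = FALSE)
  }
  structure(
    list(
      kernel = dispersal_kernel(family, theta_hat),
      sse = sse_hat,
      n_pos = n_pos, n_neg = n_neg,
      labels = labels,
      seed_ids = seed_ids,
      start_year = start_year,
      reference_year = reference_year,
      search = list(lower = lower, upper = upper, n_grid = n_grid, tol = tol),
      grid = tibble::tibble(theta = grid, sse = sse_grid),
      boundary = boundary
    ),
    class = "kernel_fit"
  )
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf(
    "<kernel_fit> %s kernel, theta = %.6g (SSE = %.4f; %d positive / %d negative labels)\n",
    x$kernel$family, x$kernel$theta, x$sse, x$n_pos, x$n_neg))
  if (x$boundary) cat("  ! optimum at search boundary\n")
  invisible(x)
}

#' @method tidy kernel_fit
#' @export
tidy.kernel_fit <- function(x, ...) {
  tibble::tibble(
    term = switch(x$kernel$family, exponential = "alpha", normal = "beta",
                  cauchy = "gamma"),
    family = x$kernel$family,
    estimate = x$kernel$theta,
    sse = x$sse
  )
}

#' @method glance kernel_fit
#' @export
glance.kernel_fit <- function(x, ...) {
  tibble::tibble(
    family = x$kernel$family,
    theta = x$kernel$theta,
    sse = x$sse,
    n_pos = x$n_pos,
    n_neg = x$n_neg,
    start_year = x$start_year,
    reference_year = x$reference_year,
    boundary = x$boundary
  )
}

#' @describeIn fit_kernel Plot the scanned objective curve with the optimum.
#' @param object A `kernel_fit`.
#' @param ... Unused.
#' @method autoplot kernel_fit
#' @export
autoplot.kernel_fit <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(.data$theta, .data$sse)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$kernel$theta, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "theta (log scale)", y = "sum of squared residuals")
}

#' Write a plain-JSON fit report
#'
#' Records everything needed to trace a fitted kernel: family, theta, SSE,
#' label counts, search bounds and the boundary flag.
#'
#' @param fit A `kernel_fit`.
#' @param path Output JSON path.
#' @export
write_fit_report <- function(fit, path) {
  report <- list(
    family = fit$kernel$family,
    theta = fit$kernel$theta,
    sse = fit$sse,
    n_pos = fit$n_pos,
    n_neg = fit$n_neg,
    seed_ids = as.list(fit$seed_ids),
    start_year = fit$start_year,
    reference_year = fit$reference_year,
    search_lower = fit$search$lower,
    search_upper = fit$search$upper,
    n_grid = fit$search$n_grid,
    boundary = fit$boundary
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
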