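test_that("labels reflect detections up to the reference year", {
  sv <- tibble::tibble(
    location_id = c("a", "b", "b", "c", "d"),
    year = c(2010L, 2012L, 2014L, 2016L, 2013L),
    outcome = c("detected", "not_detected", "detected", "detected",
                "not_detected")
  )
  lab <- build_labels(sv, 2015)
  expect_equal(lab$label[lab$location_id == "a"], 1L)
  # detection overrides an earlier negative
  expect_equal(lab$label[lab$location_id == "b"], 1L)
  # detection after the reference year does not count
  expect_false("c" %in% lab$location_id)
  expect_equal(lab$label[lab$location_id == "d"], 0L)
  expect_equal(attr(lab, "reference_year"), 2015L)
})

test_that("same-year conflicting records warn and detection wins", {
  sv <- tibble::tibble(
    location_id = c("a", "a"),
    year = c(2012L, 2012L),
    outcome = c("not_detected", "detected")
  )
  expect_warning(lab <- build_labels(sv, 2015), "detection wins")
  expect_equal(lab$label, 1L)
})

test_that("outcome strings are case-insensitive and validated", {
  sv <- tibble::tibble(location_id = "a", year = 2010L, outcome = "Detected")
  expect_equal(validate_surveys(sv)$outcome, "detected")
  sv$outcome <- "maybe"
  expect_error(validate_surveys(sv), "invalid outcome")
})

test_that("survey CSV IO round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_surveys(demo_surveys(), path)
  expect_equal(as.data.frame(read_surveys(path)),
               as.data.frame(demo_surveys()))
})

test_that("objective limit cases behave as the model dictates", {
  net <- random_network(10, seed = 12)
  D <- distance_matrix(net)
  # labels only at the seed: probability there is 1 for any theta
  seed_only <- tibble::tibble(location_id = "seed", label = 1L)
  for (th in c(0.01, 1, 50)) {
    expect_equal(sse_objective(th, "cauchy", D, seed_only, "seed", 2003,
                               reference_year = 2015), 0)
  }
  # a single 0-labelled far city: objective vanishes as theta -> 0+
  far <- tibble::tibble(location_id = net$id[which.max(D["seed", ])],
                        label = 0L)
  expect_lt(sse_objective(1e-6, "cauchy", D, far, "seed", 2003,
                          reference_year = 2015), 1e-6)
})

test_that("objective is finite, continuous-looking and minimised near truth", {
  net <- random_network(80, seed = 21)
  D <- distance_matrix(net)
  true_gamma <- 12
  sv <- simulate_survey_data(net, dispersal_kernel("cauchy", true_gamma),
                             2003, 2015, rule = "threshold")
  labels <- build_labels(sv, 2015)
  grid <- exp(seq(log(0.1), log(500), length.out = 60))
  sse <- vapply(grid, function(th) {
    sse_objective(th, "cauchy", D, labels, "seed", 2003)
  }, numeric(1))
  expect_true(all(is.finite(sse)))
  best <- grid[which.min(sse)]
  expect_lt(abs(best - true_gamma) / true_gamma, 0.5)
})

test_that("fit_kernel beats random thetas and recovers a known gamma", {
  net <- random_network(100, seed = 31)
  D <- distance_matrix(net)
  sv <- simulate_survey_data(net, dispersal_kernel("cauchy", 12), 2003, 2015)
  fit <- fit_kernel(net, sv, family = "cauchy", seed_ids = "seed",
                    start_year = 2003, reference_year = 2015, D = D)
  expect_s3_class(fit, "kernel_fit")
  expect_lt(abs(fit$kernel$theta - 12) / 12, 0.15)
  labels <- build_labels(sv, 2015)
  random_thetas <- withr::with_seed(99, exp(runif(100, log(1e-6), log(1e3))))
  random_sse <- vapply(random_thetas, function(th) {
    sse_objective(th, "cauchy", D, labels, "seed", 2003)
  }, numeric(1))
  expect_true(all(fit$sse <= random_sse + 1e-12))
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_kernel(demo_cities(), demo_surveys(), family = "cauchy",
                    seed_ids = "moscow", start_year = 2003,
                    reference_year = 2015)
  td <- tidy(fit)
  expect_named(td, c("term", "family", "estimate", "sse"))
  expect_equal(td$term, "gamma")
  gl <- glance(fit)
  expect_equal(gl$n_pos, 10L)
  expect_equal(gl$n_neg, 11L)
  expect_false(gl$boundary)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$theta, fit$kernel$theta, tolerance = 1e-12)
  expect_equal(rep$n_pos, 10L)
})

test_that("degenerate label sets and missing locations are hard errors", {
  net <- random_network(10, seed = 41)
  all_pos <- tibble::tibble(location_id = net$id, year = 2010L,
                            outcome = "detected")
  expect_error(
    fit_kernel(net, all_pos, family = "cauchy", seed_ids = "seed",
               start_year = 2003, reference_year = 2015),
    "degenerate label set"
  )
  sv <- tibble::tibble(location_id = c("seed", "ghost"),
                       year = c(2005L, 2010L),
                       outcome = c("detected", "not_detected"))
  expect_error(
    fit_kernel(net, sv, family = "cauchy", seed_ids = "seed",
               start_year = 2003, reference_year = 2015),
    "missing from the network"
  )
})

test_that("an unresolvable fit lands on the boundary with a warning", {
  # one positive at the seed, one negative far away: the objective decreases
  # monotonically as the kernel narrows, so the optimum is the lower bound
  loc <- tibble::tibble(
    id = c("seed", "far"), name = id, country = "x", region = "x",
    lat = c(55, 52.8), lon = c(37, 37)
  )
  sv <- tibble::tibble(location_id = c("seed", "far"),
                       year = 2005L,
                       outcome = c("detected", "not_detected"))
  expect_warning(
    fit <- fit_kernel(loc, sv, family = "cauchy", seed_ids = "seed",
                      start_year = 2003, reference_year = 2015, n_grid = 50),
    "boundary|bounds"
  )
  expect_true(fit$boundary)
})
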