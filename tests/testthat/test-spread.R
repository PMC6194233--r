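kernel_matrix <- function(kernel, D) kernel_prob(kernel, D)

test_that("annual_step reproduces hand-computed complement products", {
  # two cities: certain source transmits with f = 0.1
  D <- matrix(c(0, 50, 50, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  k <- dispersal_kernel("cauchy", 50 / 3) # f(50) = 1 / (1 + 9) = 0.1
  nxt <- annual_step(c(a = 1, b = 0), D, k)
  expect_equal(unname(nxt), c(1, 0.1))
  # all-zero state stays all-zero
  expect_equal(unname(annual_step(c(a = 0, b = 0), D, k)), c(0, 0))
})

test_that("three certain sources at f = 0.1 each give 1 - 0.9^3", {
  # four cities, three sources equidistant from the target
  ids <- c("s1", "s2", "s3", "t")
  D <- matrix(1000, 4, 4, dimnames = list(ids, ids)) # sources far apart
  D[, "t"] <- D["t", ] <- 50
  diag(D) <- 0
  k <- dispersal_kernel("cauchy", 50 / 3)
  p <- annual_step(setNames(c(1, 1, 1, 0), ids), D, k)
  expect_equal(unname(p["t"]), 1 - 0.9^3)
})

test_that("annual_step equals exhaustive event enumeration on 3-node networks", {
  for (s in 1:20) {
    net <- random_network(3, seed = s)
    D <- distance_matrix(net)
    k <- random_kernel(s + 100)
    F <- kernel_matrix(k, D)
    p <- withr::with_seed(s, runif(3))
    names(p) <- net$id
    expect_lt(max(abs(unname(annual_step(p, D, k)) - enumerate_step(p, F))),
              1e-12)
  }
})

test_that("two-step composition matches the exact infestation process", {
  for (s in 1:12) {
    net <- random_network(3, seed = s, box_half_km = 150)
    D <- distance_matrix(net)
    k <- random_kernel(s + 40)
    F <- kernel_matrix(k, D)
    traj <- simulate_spread(net, k, "seed", 2003, 2005, D = D)
    exact <- enumerate_spread(F, seed_idx = 1, n_steps = 2)
    # absolute tolerance: probabilities range down to ~1e-20 for thin tails
    expect_lt(max(abs(unname(probabilities_at(traj, 2005)) - exact)), 1e-12)
  }
})

test_that("log-space and direct products agree on random 50-node networks", {
  for (s in 1:5) {
    net <- random_network(50, seed = s)
    D <- distance_matrix(net)
    k <- random_kernel(s + 7)
    p <- withr::with_seed(s, runif(50))
    names(p) <- net$id
    a <- annual_step(p, D, k, method = "log")
    b <- annual_step(p, D, k, method = "direct")
    expect_lt(max(abs(a - b)), 1e-12)
  }
})

test_that("trajectories are monotone non-decreasing for every location", {
  for (s in 1:100) {
    net <- random_network(12, seed = s)
    k <- random_kernel(s)
    traj <- simulate_spread(net, k, "seed", 2003, 2010)
    expect_true(all(apply(traj$P, 1, function(x) all(diff(x) >= -1e-14))))
    expect_true(all(traj$P >= 0 & traj$P <= 1))
    expect_true(all(traj$P["seed", ] == 1))
  }
})

test_that("relabelling and reordering locations permutes outputs identically", {
  net <- random_network(20, seed = 5)
  k <- dispersal_kernel("cauchy", 15)
  traj <- simulate_spread(net, k, "seed", 2003, 2012)
  perm <- withr::with_seed(9, sample(nrow(net)))
  shuffled <- net[perm, ]
  traj2 <- simulate_spread(shuffled, k, "seed", 2003, 2012)
  expect_equal(traj2$P, traj$P[perm, ], tolerance = 1e-14)
})

test_that("adding a city never decreases any other city's probability", {
  net <- random_network(25, seed = 8)
  k <- dispersal_kernel("cauchy", 20)
  base <- simulate_spread(net, k, "seed", 2003, 2012)
  extra <- net[1, ]
  extra$id <- "extra"; extra$name <- "extra"
  extra$lat <- extra$lat + 0.5; extra$lon <- extra$lon + 0.5
  bigger <- simulate_spread(rbind(net, extra), k, "seed", 2003, 2012)
  expect_true(all(bigger$P[net$id, ] >= base$P - 1e-14))
})

test_that("simulation start and end conditions behave as specified", {
  net <- random_network(10, seed = 2)
  k <- dispersal_kernel("exponential", 0.01)
  # zero-length horizon: trajectory is just the seed indicator
  traj <- simulate_spread(net, k, "seed", 2003, 2003)
  expect_equal(unname(probabilities_at(traj, 2003)),
               as.numeric(net$id == "seed"))
  expect_error(simulate_spread(net, k, "nowhere", 2003, 2010), "unknown seed")
  expect_error(simulate_spread(net, k, "seed", 2010, 2003), "start_year")
  expect_error(annual_step(runif(5), distance_matrix(net), k),
               "does not match")
})

test_that("conditioning overwrites detections and only detections", {
  net <- random_network(15, seed = 3)
  k <- dispersal_kernel("cauchy", 10)
  traj <- simulate_spread(net, k, "seed", 2003, 2015)
  p <- probabilities_at(traj, 2015)
  # empty detection set leaves the vector unchanged
  expect_equal(condition_on_detections(traj, character(0), 2015), p)
  # all detected gives all ones
  expect_equal(unname(condition_on_detections(traj, net$id, 2015)),
               rep(1, 15))
  some <- net$id[c(3, 7)]
  cond <- condition_on_detections(traj, some, 2015)
  expect_equal(unname(cond[some]), c(1, 1))
  expect_equal(cond[setdiff(net$id, some)], p[setdiff(net$id, some)])
  # survey-table form filters to detections at or before the year
  sv <- tibble::tibble(location_id = net$id[c(2, 4)],
                       year = c(2010L, 2016L),
                       outcome = "detected")
  cond2 <- condition_on_detections(traj, sv, 2015)
  expect_equal(unname(cond2[net$id[2]]), 1)
  expect_equal(cond2[net$id[4]], p[net$id[4]]) # detected only after 2015
  expect_error(condition_on_detections(traj, "nope", 2015), "unknown")
  expect_error(probabilities_at(traj, 1999), "outside")
})

test_that("forecasting from a conditioned state is absorbing and consistent", {
  net <- random_network(15, seed = 6)
  k <- dispersal_kernel("cauchy", 10)
  traj <- simulate_spread(net, k, "seed", 2003, 2017)
  p0 <- condition_on_detections(traj, net$id[1:5], 2017)
  # identity horizon
  fc0 <- forecast_spread(net, k, p0, 2017, 2017)
  expect_equal(probabilities_at(fc0, 2017), p0)
  # all-ones stays all-ones
  ones <- setNames(rep(1, 15), net$id)
  fc1 <- forecast_spread(net, k, ones, 2017, 2022)
  expect_true(all(fc1$P == 1))
  # forecasting without conditioning continues the original recursion
  fc <- forecast_spread(net, k, probabilities_at(traj, 2017), 2017, 2022)
  long <- simulate_spread(net, k, "seed", 2003, 2022)
  expect_equal(probabilities_at(fc, 2022), probabilities_at(long, 2022),
               tolerance = 1e-12)
})

test_that("conditioning during the recursion pins detected cities to 1", {
  net <- random_network(10, seed = 4)
  k <- dispersal_kernel("normal", 1e-4)
  sv <- tibble::tibble(location_id = net$id[4], year = 2008L,
                       outcome = "detected")
  traj <- simulate_spread(net, k, "seed", 2003, 2012,
                          condition_detections = sv)
  expect_true(all(traj$P[net$id[4], as.character(2008:2012)] == 1))
  expect_lt(traj$P[net$id[4], "2007"], 1)
})

test_that("tidy trajectories are long, complete and round-trip to CSV", {
  net <- random_network(8, seed = 1)
  traj <- simulate_spread(net, dispersal_kernel("cauchy", 12), "seed",
                          2003, 2007)
  td <- tidy(traj)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8 * 5)
  expect_named(td, c("id", "year", "probability", "percent"))
  expect_equal(td$percent, floor(100 * td$probability + 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$probability, td$probability, tolerance = 1e-12)
})
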