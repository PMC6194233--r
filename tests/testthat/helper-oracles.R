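# Independent oracles used across the suite.

# Haversine great-circle distance -- numerically stabler equivalent of the
# spherical law of cosines, written independently of the package's formula.
haversine_km <- function(lat1, lon1, lat2, lon2, r = 6371.0088) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Exact multi-year spread probabilities by exhaustive enumeration of the
# infestation process: the state is the set of infested cities; each year
# every infested city i independently infects each city j with probability
# F[i, j] (F[i, i] = 1 keeps establishment absorbing). Marginal P(j infested
# after n_steps) is computed by full enumeration over the 2^n subset states.
# Feasible only for tiny n -- that is the point.
enumerate_spread <- function(F, seed_idx, n_steps) {
  n <- nrow(F)
  states <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  n_states <- nrow(states)
  start <- seq_len(n) %in% seed_idx
  prob <- as.numeric(apply(states, 1, function(s) identical(as.logical(s), start)))
  # transition probability from state s to state t in one year
  trans <- matrix(0, n_states, n_states)
  for (si in seq_len(n_states)) {
    s <- states[si, ]
    # probability each city is infested at year end
    p_inf <- numeric(n)
    for (j in seq_len(n)) {
      if (s[j]) {
        p_inf[j] <- 1 # absorbing
      } else {
        p_inf[j] <- 1 - prod(1 - F[s, j])
      }
    }
    for (ti in seq_len(n_states)) {
      t <- states[ti, ]
      if (any(s & !t)) next # infested cities never recover
      trans[si, ti] <- prod(ifelse(t, p_inf, 1 - p_inf))
    }
  }
  for (k in seq_len(n_steps)) prob <- as.numeric(prob %*% trans)
  # marginal per city
  unname(colSums(states * prob))
}

# Single annual step by enumeration over source-infestation patterns:
# each source i is independently "infested" with probability p[i] and, if
# infested, transmits to j with probability F[i, j].
enumerate_step <- function(p, F) {
  n <- length(p)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  out <- numeric(n)
  for (j in seq_len(n)) {
    no_arrival <- 0
    for (si in seq_len(nrow(subsets))) {
      s <- subsets[si, ]
      w <- prod(ifelse(s, p, 1 - p))
      no_arrival <- no_arrival + w * prod(1 - F[s, j])
    }
    out[j] <- 1 - no_arrival
  }
  out
}

random_network <- function(n, seed, box_half_km = 800) {
  generate_city_network(n, seed = seed, box_half_km = box_half_km)
}

random_kernel <- function(seed) {
  withr::with_seed(seed, {
    family <- sample(c("exponential", "normal", "cauchy"), 1)
    theta <- switch(family,
                    exponential = stats::runif(1, 0.001, 0.1),
                    normal = stats::runif(1, 1e-5, 1e-3),
                    cauchy = stats::runif(1, 2, 100))
  })
  dispersal_kernel(family, theta)
}
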