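# Shared fixtures: tiny hand-built tables plus a small simulated region.

tiny_zones <- function(n = 3) {
  as_zones(tibble::tibble(
    zone_id = LETTERS[seq_len(n)],
    x = seq_len(n), y = rep(0, n),
    households = 100 * seq_len(n),
    frac_low_income = seq(0.1, 0.1 * n, by = 0.1)
  ))
}

tiny_parks <- function(n = 2, acres = NULL) {
  as_resources(tibble::tibble(
    resource_id = paste0("p", seq_len(n)),
    x = seq_len(n), y = rep(1, n),
    acres = acres %||% rep(4, n),
    playground = rep(TRUE, n), volleyball = rep(FALSE, n),
    basketball = rep(FALSE, n), tennis = rep(FALSE, n)
  ), "park")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Auto-only skim rows for every zone-resource pair, times supplied as a
# zones x resources matrix of minutes.
auto_skims <- function(zones, resources, t_auto) {
  tidyr::expand_grid(zone_id = zones$zone_id,
                     resource_id = resources$resource_id) |>
    dplyr::mutate(
      t_auto = as.vector(t(t_auto)),
      t_transit_iv = NA_real_, wt = NA_real_, at = NA_real_,
      t_walk = NA_real_, d_walk = NA_real_
    ) |>
    as_skims()
}

one_pair_skim <- function(t_auto = NA, t_transit_iv = NA, wt = NA, at = NA,
                          t_walk = NA, d_walk = NA) {
  as_skims(tibble::tibble(
    zone_id = "A", resource_id = "p1",
    t_auto = t_auto, t_transit_iv = t_transit_iv, wt = wt, at = at,
    t_walk = t_walk, d_walk = d_walk
  ))
}

# Small region for fast end-to-end tests.
small_config <- function(seed = 11, ...) {
  region_config(
    n_zones = 9, n_resources = c(park = 6, grocery = 4, library = 3),
    extent_km = c(9, 6), n_device_trips = 20000, n_trips = 1000,
    seed = seed, ...
  )
}

# Simulate a small dataset and fit; used by several estimation tests.
small_fit <- function(seed = 11, rtype = "park", impedance = "t_auto",
                      n_trips = 1000) {
  cfg <- small_config(seed)
  sim <- simulate_region(cfg)
  trips <- sample_trips(sim$flows[[rtype]], n_trips, seed = seed + 100)
  alts <- sample_alternatives(trips, sim$resources[[rtype]], cfg$n_alt,
                              seed = seed + 200)
  # compact spec: small regions cannot guarantee variation in every
  # Bernoulli amenity, so tiny fixtures model impedance + log size only
  spec <- model_spec(rtype, impedance = impedance,
                     terms = tibble::tibble(attribute = "acres",
                                            transform = "log"))
  data <- attach_covariates(alts, sim$skims[[rtype]], sim$resources[[rtype]],
                            spec, quiet = TRUE)
  list(sim = sim, data = data, fit = mnl_fit(data), spec = spec)
}
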