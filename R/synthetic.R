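# Synthetic region generator: zones, resources, distance-derived travel
# skims, and visit flows drawn from a known ground-truth destination
# choice model. The generated region emulates a linear-corridor county --
# zones on a jittered grid, resources concentrated toward a transit spine
# -- so every pipeline stage can be exercised and validated by parameter
# recovery without any external data.

#' Ground-truth destination-choice coefficients per resource type
#'
#' Default true coefficients for the synthetic generator, set to published
#' full-specification ("impedance + all attributes") estimates for each
#' resource type so that recovery tests target field-realistic magnitudes.
#' The impedance coefficient is on drive minutes (`t_auto`) or on the
#' mode-choice logsum (`mcls`).
#'
#' @param rtype One of `resource_types()`.
#' @param impedance `"t_auto"` or `"mcls"`.
#' @return Named coefficient vector aligned with
#'   `covariate_names(model_spec(rtype, impedance))`.
#' @export
true_coefficients <- function(rtype, impedance = c("t_auto", "mcls")) {
  rtype <- match.arg(rtype, resource_types())
  impedance <- match.arg(impedance)
  imp <- switch(rtype,
    park = c(t_auto = -0.267, mcls = 9.547),
    grocery = c(t_auto = -0.270, mcls = 9.643),
    library = c(t_auto = -0.313, mcls = 11.195)
  )[impedance]
  gamma <- switch(rtype,
    park = c(log_acres = 1.307, playground = 4.467, volleyball = -0.555,
             basketball = -0.508, tennis = -0.881),
    grocery = c(n_registers = 0.087, n_selfcheckout = 0.020,
                convenience = -1.343, other_nonstandard = -1.418,
                pharmacy = 0.330, ethnic_market = -0.887,
                other_merchandise = 0.909),
    library = c(log_sqft = 1.219, offers_classes = -0.819,
                genealogy = -0.867)
  )
  c(setNames(imp, impedance), gamma)
}

#' Configuration of a synthetic region
#'
#' Defaults describe a desk-scale corridor region: 50 zones on a jittered
#' grid over a 30 x 12 km extent, 30 parks / 12 grocery stores / 8
#' libraries concentrated toward a central east-west spine, lognormal
#' household counts, a low-income share that declines away from the spine,
#' distance-derived skims (circuity-factored Euclidean distances, transit
#' only near the spine), and 100,000 device trips per resource type drawn
#' from the ground-truth choice model, of which 10,000 are sampled for
#' estimation with 10 random alternatives each.
#'
#' @param n_zones Number of zones.
#' @param n_resources Named vector of resource counts per type.
#' @param extent_km Region extent `c(x, y)` in km.
#' @param hh_meanlog,hh_sdlog Lognormal parameters of zone household counts.
#' @param income_intercept,income_slope,income_noise_sd Logistic model of
#'   the low-income fraction as a function of distance to the spine (km).
#' @param park_acres_meanlog,park_acres_sdlog Lognormal park size (acres).
#' @param library_sqft_meanlog,library_sqft_sdlog Lognormal library size.
#' @param grocery_registers_rate,grocery_selfcheckout_rate Poisson rates
#'   for register counts (registers are 1 + Poisson).
#' @param amenity_probs Named list of Bernoulli probabilities for the flag
#'   attributes of each resource type.
#' @param circuity Network circuity factor applied to Euclidean distance.
#' @param auto_speed_kmh,walk_speed_kmh,transit_speed_kmh Speeds.
#' @param terminal_min Fixed auto terminal time, minutes.
#' @param headway_min Transit headway (wait time is half the headway).
#' @param corridor_halfwidth_km Transit available only when both endpoints
#'   lie within this distance of the spine.
#' @param max_walk_km,max_total_min Path validity limits: walking legs no
#'   longer than 10 km, total time no more than 2 hours.
#' @param truth_impedance Impedance kind of the ground-truth model.
#' @param truth Named list of true coefficient vectors per type
#'   (default [true_coefficients()]).
#' @param n_device_trips Device-trip volume behind the flow table.
#' @param n_trips Estimation trips sampled from the flows.
#' @param n_alt Sampled non-chosen alternatives per trip.
#' @param seed Global seed; stages derive child seeds by fixed offsets.
#' @return A `region_config` list.
#' @export
region_config <- function(n_zones = 50,
                          n_resources = c(park = 30, grocery = 12, library = 8),
                          extent_km = c(30, 12),
                          hh_meanlog = log(500), hh_sdlog = 0.6,
                          income_intercept = -1.1, income_slope = -0.2,
                          income_noise_sd = 0.35,
                          park_acres_meanlog = log(8), park_acres_sdlog = 1.1,
                          library_sqft_meanlog = log(20000),
                          library_sqft_sdlog = 0.7,
                          grocery_registers_rate = 7,
                          grocery_selfcheckout_rate = 3,
                          amenity_probs = list(
                            park = c(playground = 0.6, volleyball = 0.2,
                                     basketball = 0.3, tennis = 0.25),
                            grocery = c(convenience = 0.2, other_nonstandard = 0.1,
                                        pharmacy = 0.4, ethnic_market = 0.1,
                                        other_merchandise = 0.35),
                            library = c(offers_classes = 0.7, genealogy = 0.5)
                          ),
                          circuity = 1.3, auto_speed_kmh = 45,
                          walk_speed_kmh = 4.8, transit_speed_kmh = 30,
                          terminal_min = 2, headway_min = 15,
                          corridor_halfwidth_km = 2,
                          max_walk_km = 10, max_total_min = 120,
                          truth_impedance = "t_auto",
                          truth = NULL,
                          n_device_trips = 100000, n_trips = 10000,
                          n_alt = 10, seed = 42) {
  cfg <- as.list(environment())
  if (is.null(cfg$truth)) {
    cfg$truth <- setNames(
      lapply(resource_types(), true_coefficients, impedance = truth_impedance),
      resource_types())
  }
  stopifnot(n_zones >= 1, all(n_resources >= 1), all(extent_km > 0),
            auto_speed_kmh > 0, walk_speed_kmh > 0, transit_speed_kmh > 0,
            circuity >= 1, n_trips >= 1, n_device_trips >= 1, n_alt >= 1)
  if (is.null(cfg$seed)) stop_validation("seed is mandatory in region_config")
  if (prod(extent_km) < n_zones * 0.25) {
    stop_validation("extent too small for n_zones (need at least 0.25 km^2 per zone)")
  }
  structure(cfg, class = "region_config")
}

spine_y <- function(config) config$extent_km[2] / 2

#' Generate zones and resources for a synthetic region
#'
#' Zones sit on a jittered rectangular grid; resources are placed with
#' density increasing toward the central spine, with attributes drawn from
#' the configured distributions. Reproducible under the config seed.
#'
#' @param config A [region_config()].
#' @return List with elements `zones` (tibble) and `resources` (named list
#'   of tibbles per resource type).
#' @export
gen_region <- function(config) {
  stopifnot(inherits(config, "region_config"))
  ex <- config$extent_km[1]; ey <- config$extent_km[2]
  withr::with_seed(as.integer(config$seed), {
    nx <- ceiling(sqrt(config$n_zones * ex / ey))
    ny <- ceiling(config$n_zones / nx)
    cx <- ex / nx; cy <- ey / ny
    grid <- tidyr::expand_grid(ix = seq_len(nx) - 0.5, iy = seq_len(ny) - 0.5)
    grid <- grid[seq_len(config$n_zones), ]
    n <- config$n_zones
    dist_spine <- numeric(n)
    zones <- tibble::tibble(
      zone_id = sprintf("z%03d", seq_len(n)),
      x = grid$ix * cx + runif(n, -0.3 * cx, 0.3 * cx),
      y = grid$iy * cy + runif(n, -0.3 * cy, 0.3 * cy),
      households = round(rlnorm(n, config$hh_meanlog, config$hh_sdlog))
    )
    dist_spine <- abs(zones$y - spine_y(config))
    zones$frac_low_income <- plogis(config$income_intercept +
                                      config$income_slope * dist_spine +
                                      rnorm(n, 0, config$income_noise_sd))
    zones <- as_zones(zones)

    resources <- lapply(resource_types(), function(rt) {
      m <- config$n_resources[[rt]]
      base <- tibble::tibble(
        resource_id = sprintf("%s%03d", substr(rt, 1, 1), seq_len(m)),
        x = runif(m, 0, ex),
        y = pmin(pmax(spine_y(config) + rnorm(m, 0, ey / 4), 0), ey)
      )
      probs <- config$amenity_probs[[rt]]
      for (a in names(probs)) base[[a]] <- rbinom(m, 1, probs[[a]]) == 1
      if (rt == "park") {
        base$acres <- rlnorm(m, config$park_acres_meanlog, config$park_acres_sdlog)
      } else if (rt == "library") {
        base$sqft <- rlnorm(m, config$library_sqft_meanlog, config$library_sqft_sdlog)
      } else {
        base$n_registers <- 1 + rpois(m, config$grocery_registers_rate)
        base$n_selfcheckout <- rpois(m, config$grocery_selfcheckout_rate)
      }
      as_resources(base, rt)
    })
    names(resources) <- resource_types()
    list(zones = zones, resources = resources)
  })
}

#' Generate distance-derived travel skims
#'
#' Deterministic given the region: over-the-road distance is Euclidean
#' distance times a circuity factor; auto time adds a fixed terminal time;
#' walking is available up to the walking-distance limit; transit is
#' available only when both endpoints lie near the spine, with in-vehicle
#' time along the spine, wait time of half the headway, and access/egress
#' walking from the perpendicular offsets. Availability enforces the path
#' limits (walk legs within the walking limit, total time within the
#' two-hour cap).
#'
#' @param zones Zone tibble.
#' @param resources Resource tibble (one type).
#' @param config A [region_config()].
#' @return Validated skim tibble over all pairs.
#' @export
gen_skims <- function(zones, resources, config) {
  stopifnot(inherits(config, "region_config"))
  sp <- spine_y(config)
  pairs <- tidyr::expand_grid(iz = seq_len(nrow(zones)),
                              ir = seq_len(nrow(resources)))
  zx <- zones$x[pairs$iz]; zy <- zones$y[pairs$iz]
  rx <- resources$x[pairs$ir]; ry <- resources$y[pairs$ir]
  d_km <- sqrt((zx - rx)^2 + (zy - ry)^2) * config$circuity

  t_auto <- d_km / config$auto_speed_kmh * 60 + config$terminal_min
  t_walk <- d_km / config$walk_speed_kmh * 60
  d_walk_mi <- d_km / 1.609344
  avail_walk <- d_km <= config$max_walk_km & t_walk <= config$max_total_min

  near_z <- abs(zy - sp) <= config$corridor_halfwidth_km
  near_r <- abs(ry - sp) <= config$corridor_halfwidth_km
  access_km <- (abs(zy - sp) + abs(ry - sp)) * config$circuity
  at <- access_km / config$walk_speed_kmh * 60
  iv <- abs(zx - rx) / config$transit_speed_kmh * 60
  wt <- rep(config$headway_min / 2, length(iv))
  total <- iv + wt + at
  avail_transit <- near_z & near_r & access_km <= config$max_walk_km &
    total <= config$max_total_min

  as_skims(tibble::tibble(
    zone_id = zones$zone_id[pairs$iz],
    resource_id = resources$resource_id[pairs$ir],
    t_auto = t_auto,
    t_transit_iv = ifelse(avail_transit, iv, NA_real_),
    wt = ifelse(avail_transit, wt, NA_real_),
    at = ifelse(avail_transit, at, NA_real_),
    t_walk = ifelse(avail_walk, t_walk, NA_real_),
    d_walk = ifelse(avail_walk, d_walk_mi, NA_real_)
  ))
}

#' Generate visit flows from a ground-truth choice model
#'
#' Each device trip draws its origin zone with probability proportional to
#' households and its destination from the full-choice-set multinomial
#' logit probabilities at the true coefficients (destinations are chosen
#' over the complete resource inventory, not a sampled subset -- sampling
#' of alternatives is an estimation device only).
#'
#' @param zones,resources,skims Region tables (one resource type).
#' @param truth Named true coefficient vector aligned with
#'   `covariate_names(model_spec(rtype, impedance))`.
#' @param coeffs [mode_coefficients()] (used when the truth impedance is
#'   the mode-choice logsum).
#' @param n_trips Number of device trips.
#' @param seed Integer seed.
#' @param impedance Impedance kind of the truth model.
#' @return Validated flow tibble (pairs with positive counts).
#' @export
gen_flows <- function(zones, resources, skims, truth,
                      coeffs = mode_coefficients(), n_trips = 100000, seed,
                      impedance = c("t_auto", "mcls")) {
  impedance <- match.arg(impedance)
  if (missing(seed)) stop_validation("seed is required for gen_flows")
  rtype <- unique(resources$rtype)
  spec <- model_spec(rtype, impedance = impedance)
  covars <- covariate_names(spec)
  if (!all(covars %in% names(truth))) {
    stop_validation("truth coefficients do not match the covariates of the spec")
  }
  sk <- complete_skims(as_skims(skims), zones, resources)
  imp <- impedance_matrix(sk, coeffs, kind = impedance)
  attrs <- resources[c("resource_id", spec$terms$attribute)]
  for (i in seq_len(nrow(spec$terms))) {
    a <- spec$terms$attribute[i]
    v <- as.numeric(attrs[[a]])
    attrs[[a]] <- if (spec$terms$transform[i] == "log") log(v) else v
  }
  names(attrs) <- c("resource_id", covars[-1])
  long <- dplyr::left_join(imp, attrs, by = "resource_id")
  names(long)[names(long) == "impedance"] <- covars[1]
  V <- drop(as.matrix(long[covars]) %*% truth[covars])
  V[!long$reachable] <- -Inf
  vm <- matrix(V, nrow = nrow(zones), byrow = TRUE)

  withr::with_seed(as.integer(seed), {
    zone_trips <- drop(rmultinom(1, n_trips, prob = pmax(zones$households, 0)))
    counts <- matrix(0L, nrow(zones), nrow(resources))
    for (i in seq_len(nrow(zones))) {
      if (zone_trips[i] == 0) next
      v <- vm[i, ]
      if (all(!is.finite(v))) {
        stop_validation(sprintf("zone %s has no reachable resource", zones$zone_id[i]))
      }
      p <- exp(v - max(v[is.finite(v)]))
      p[!is.finite(p)] <- 0
      counts[i, ] <- drop(rmultinom(1, zone_trips[i], prob = p))
    }
    flows <- tibble::tibble(
      zone_id = rep(zones$zone_id, times = nrow(resources)),
      resource_id = rep(resources$resource_id, each = nrow(zones)),
      count = as.vector(counts)
    )
    as_flows(flows[flows$count > 0, ], zones, resources)
  })
}

#' Simulate a complete synthetic region
#'
#' Runs [gen_region()], [gen_skims()] and [gen_flows()] for every resource
#' type. Stages use child seeds derived from the config seed by fixed
#' offsets, so each stage is independently reproducible. When `out_dir` is
#' given, writes the four standard CSVs per type (zones, resources, skims,
#' flows) plus `truth.json` recording the ground-truth coefficients for
#' recovery tests.
#'
#' @param config A [region_config()].
#' @param out_dir Optional output directory.
#' @param coeffs [mode_coefficients()] used for flow generation when the
#'   truth impedance is the mode-choice logsum.
#' @return List with `zones`, `resources`, `skims`, `flows` (lists per
#'   type), `truth`, and `config`.
#' @export
simulate_region <- function(config = region_config(), out_dir = NULL,
                            coeffs = mode_coefficients()) {
  region <- gen_region(config)
  skims <- lapply(region$resources, gen_skims, zones = region$zones,
                  config = config)
  offsets <- setNames(seq_along(resource_types()) + 10, resource_types())
  flows <- lapply(resource_types(), function(rt) {
    gen_flows(region$zones, region$resources[[rt]], skims[[rt]],
              truth = config$truth[[rt]], coeffs = coeffs,
              n_trips = config$n_device_trips,
              seed = as.integer(config$seed) + offsets[[rt]],
              impedance = config$truth_impedance)
  })
  names(flows) <- resource_types()
  out <- list(zones = region$zones, resources = region$resources,
              skims = skims, flows = flows, truth = config$truth,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_zones(out$zones, file.path(out_dir, "zones.csv"))
    for (rt in resource_types()) {
      write_resources(out$resources[[rt]],
                      file.path(out_dir, sprintf("resources_%s.csv", rt)), rt)
      write_skims(out$skims[[rt]], file.path(out_dir, sprintf("skims_%s.csv", rt)))
      write_flows(out$flows[[rt]], file.path(out_dir, sprintf("flows_%s.csv", rt)))
    }
    jsonlite::write_json(lapply(out$truth, as.list),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
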