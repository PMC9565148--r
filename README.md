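# utilaccess

Utility-based accessibility to community resources — parks, grocery
stores, and libraries — estimated from zone-to-resource visit flows.

## The problem

Spatial public-health and planning analyses usually measure access to a
community resource with a travel-time buffer: a neighborhood "has access"
to a grocery store if one lies within, say, a 5-minute drive. That measure
forces the analyst to assert a mode and an arbitrary threshold, treats a
4:50 trip as categorically different from a 5:10 trip, and ignores whether
the store inside the buffer is any good. `utilaccess` implements the
alternative: estimate a destination choice model from observed visit
flows, and summarize each neighborhood's access as the *logsum* — the
expected utility of its whole choice set.

For an origin zone *i* and resource *j*, destination utility is linear in
a travel impedance and the destination's attributes,

    V_ij = beta * t_ij + X_j * gamma,

choice follows a multinomial logit, P_ij = exp(V_ij) / sum_j' exp(V_ij'),
and access is

    A_i = log( sum_j exp(V_ij) ).

The impedance t_ij can be the drive time or a *mode-choice logsum* (MCLS)
over auto, transit, and walk utilities, so the measure is sensitive to
multimodal options as well as to resource quality. Coefficients (beta,
gamma) are estimated by maximum likelihood on trips sampled from
aggregated location-based-services visit counts, each paired with ten
randomly sampled non-chosen alternatives (consistent under uniform
sampling of alternatives). Classical buffer and gravity measures, and
household-weighted equity cross-tabulations of low-access zones, are
included for comparison.

Because commercial visit-flow data cannot be redistributed, the package
ships a synthetic region generator that draws zones, resources, skims,
and flows from a known ground-truth choice model; the whole pipeline is
validated by parameter recovery against that truth.

## Worked example

```r
library(utilaccess)

cfg  <- region_config(seed = 42)          # 50 zones, 30 parks, corridor region
sim  <- simulate_region(cfg)              # zones, resources, skims, flows

trips <- sample_trips(sim$flows$park, n_trips = 10000, seed = 4301)
alts  <- sample_alternatives(trips, sim$resources$park, n_alt = 10, seed = 4302)
spec  <- model_spec("park", impedance = "mcls")
data  <- attach_covariates(alts, sim$skims$park, sim$resources$park, spec)
fit   <- mnl_fit(data)
fit
#> Multinomial logit destination choice model
#>   resource type: park; impedance: mcls
#>   mcls                        9.795  (76.714)
#>   log_acres                   1.348  (56.822)
#>   playground                  4.308  (33.433)
#>   volleyball                 -0.624  (-11.802)
#>   basketball                 -0.459  (-8.514)
#>   tennis                     -0.856  (-19.296)
#>   Num.Obs.          10000
#>   Log Likelihood    -7720.9
#>   McFadden Rho-Sq   0.678
#>   (t-statistics in parentheses)
```

People dislike distance (the MCLS enters positively: more multimodal
access, higher utility — the flows were generated with a drive-time
coefficient of −0.267, and 9.795 × −0.028 ≈ −0.274), prefer large parks
and playgrounds, and avoid single-sport facilities, matching the
generator's ground truth. Applying the model over the full inventory and
comparing with a 5-minute-walk buffer:

```r
ls  <- logsum_access(fit, sim$zones, sim$resources$park, sim$skims$park,
                     standardize = TRUE)
bf  <- buffer_access(sim$zones, sim$resources$park, sim$skims$park,
                     mode = "walk", t_star = 5)
cmp <- compare_surfaces(bf, ls, sim$zones, sim$resources$park, sim$skims$park)
head(tibble::as_tibble(cmp), 4)
#> # A tibble: 4 x 4
#>   zone_id nearest_time buffer logsum
#>   <chr>          <dbl>  <dbl>  <dbl>
#> 1 z001            47.1      0 -1.48
#> 2 z002            41.3      0 -0.553
#> 3 z003            28.4      0 -0.475
#> 4 z004            23.5      0 -0.964
```

Zones z002 and z003 are 13 walk-minutes apart in proximity terms yet have
nearly identical utility-based access, while z001 and z002 — similar by
nearest-park time — differ by almost a full util: the buffer column (all
zeros here; only 6% of zones clear the 5-minute walk threshold) cannot
express either fact. `plot_access_comparison(cmp)` draws the
corresponding scatter, and `classify_zones()` / `equity_summary()` count
households (and low-income households) that are low-access under each
definition and under both.

A file-based pipeline (`run_simulate()`, `run_build()`, `run_estimate()`,
`run_access()`, `run_equity()`, or the `inst/exec/uaccess` script with
subcommands `simulate | build-dataset | estimate | access | equity`)
composes the same steps from a YAML configuration.

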