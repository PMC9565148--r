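---
title: "Utility-based accessibility from visit flows: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Utility-based accessibility from visit flows: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utilaccess)
```

This vignette is the package's account of its science: the choice model
and its assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical and design
decisions taken where the methodology leaves them open.

## The destination choice model

A traveler in zone $i$ choosing among the resources $j \in J$ of one type
(parks, grocery stores, or libraries) is assumed to maximize a random
utility whose systematic part is linear in a travel impedance and the
destination's attributes,

$$V_{ij} = \beta\, t_{ij} + X_j \gamma,$$

giving multinomial logit choice probabilities
$P_{ij} = e^{V_{ij}} / \sum_{j'} e^{V_{ij'}}$. The log of the denominator,

$$A_i = \log \sum_{j'} e^{V_{ij'}} + C,$$

is the *logsum*: the expected maximum utility of the choice set, and the
package's utility-based accessibility measure. $C$ is unknowable because
utility is relative; the package fixes $C = 0$ and labels every logsum
surface as relative — only differences between zones are meaningful. A
`standardize` option subtracts the regional mean (by default unweighted
across zones; a household-weighted variant is available, since the
methodology does not pin down which "regional mean" is intended — the
unweighted mean is the default because the classification it feeds is
zone-level).

Assumptions worth keeping in view: one pooled model per resource type
(preferences do not vary across neighborhoods); trips originate at the
zone centroid; the decision to travel has already been made, so the model
describes *where* people go, not *whether* they go.

## The mode-choice logsum impedance

The impedance $t_{ij}$ may be the drive time in minutes (`t_auto`) or a
mode-choice logsum (`mcls`) over fixed auto, transit, and walk utilities:

* auto: $-0.028\, t^{auto}$ (utility per minute);
* transit: $-4 - 0.028\, t^{iv} - 0.056\, wt - 0.372\, at$, with wait and
  access/egress minutes weighted 2x and 13x the in-vehicle rate, typical
  of regional mode-choice models;
* walk: $-5 - 0.028\, t^{walk} - 1.12\, d$ for distances under 1.5 miles
  and $-5 - 0.028\, t^{walk} - 5.58\, d$ beyond.

These coefficients are asserted, not estimated; they are configuration
(`mode_coefficients()`) so the toolkit transfers to other regions.

Two genuinely open readings of the walk-distance term exist. The default
`"literal"` dialect applies one coefficient to the *full* distance,
selected by the 1.5-mile threshold, producing a utility discontinuity at
the threshold; the `"marginal"` dialect charges the steep rate only on
the distance beyond 1.5 miles and is continuous. The literal reading is
the default because it is the plainer reading of the stated utility
equations; since walking is rarely competitive beyond 1.5 miles under
either dialect, the choice is practically inconsequential, but it is
recorded and switchable.

A mode with no valid path contributes nothing to the logsum (the term is
dropped, not replaced by a large penalty); a pair with no available mode
at all is *unreachable* and is excluded wherever it appears. Missing skim
components always encode unavailability, never zero cost — a zero-cost
reading would dominate the logsum. When only driving is available,
$\mathrm{MCLS}_{ij} = -0.028\, t^{auto}_{ij}$ exactly; this is the source
of the near-collinearity between the MCLS and drive-time impedances on
auto-dominated data, and the package's tests verify the resulting
relationship between the two estimated impedance coefficients.

## Building the estimation dataset

Estimation data are assembled the way passively observed visit data force
one to: `sample_trips()` draws chosen (zone, resource) trips i.i.d. with
probability proportional to the observed flow counts (default 10,000
trips), and `sample_alternatives()` pairs each with 10 distinct
non-chosen resources drawn uniformly without replacement, independently
per observation. Uniform conditioning makes MNL estimation consistent on
the sampled sets without correction terms; the cost is some variance, and
the package verifies the consistency claim empirically by parameter
recovery rather than taking it on faith.

`attach_covariates()` drops an observation *whole* if any of its
alternatives is unreachable or yields a non-finite covariate, and reports
the count. Dropping whole observations (rather than thinning individual
alternatives) keeps the per-observation set size constant, which in turn
makes the equal-shares null log-likelihood exact; reference applications
of this methodology likewise retain fewer observations than they sample
without stating a rule, so the rule here is the package's own.

## Estimation, inference, and fit statistics

`mnl_fit()` maximizes the likelihood by Newton–Raphson with analytic
score $X'(y - p)$ and Hessian, step-halving on likelihood decrease, and a
BFGS rescue if the Hessian is not negative definite at an iterate.
Convergence is declared on the gradient ($\max |score| < 10^{-6}$), not
on parameter change. Start values are zero. Standard errors come from the
inverse observed information at the optimum — plain t-statistics, no
sandwich corrections. Two degenerate designs are diagnosed explicitly: a
covariate constant across alternatives within every observation is
differenced out of the logit and raises a non-identification error before
optimization; estimates diverging past $|\hat\beta| > 50$ raise a
perfect-separation error (legitimate coefficients in this domain are two
orders of magnitude smaller).

The null log-likelihood is the equal-shares value
$n \log(1/J)$ over the per-observation alternative-set size ($J = 11$
here), and McFadden's $\rho^2 = 1 - LL/LL_0$ uses it. This convention is
chosen because it exactly reproduces the published fit statistics of the
reference application from their printed log-likelihoods and observation
counts — it is the only convention that does, which the acceptance suite
checks for every published model column.

Non-nested specifications (drive time vs MCLS) are compared with the
Horowitz bound in its adjusted-$\rho^2$ form: with
$z = \bar\rho^2_H - \bar\rho^2_L \ge 0$ and
$\bar\rho^2 = 1 - (LL - K)/LL_0$,
$p \le \Phi\!\left(-\sqrt{-2 z LL_0 + (K_H - K_L)}\right)$. The result is
reported explicitly as a one-sided upper bound. On the reference park
models' printed (one-decimal) log-likelihoods the bound evaluates to
0.219; the originally reported 0.195 is consistent only with unrounded
log-likelihoods, which are unrecoverable, so the package validates the
closed form rather than that figure.

## Accessibility surfaces and equity accounting

`logsum_access()` applies a fitted model over the *full* resource
inventory — sampling of alternatives is an estimation device only.
`buffer_access()` implements the isochrone measure with a closed
threshold ($t \le t^*$; a resource exactly at the threshold is inside),
binary or cumulative. `gravity_access()` implements
$A_i = \sum_j S_j f(t_{ij}, \beta)$ with $S_j = 1$ when no size attribute
is given; the decay family is not pinned down by the methodology, so
exponential $e^{-\beta t}$ is the default and power $t^{-\beta}$ (with
$t$ floored at 1 minute to avoid the singularity) is available, both with
explicit $\beta$. With $\gamma = 0$ the logsum measure is the log of an
exponential-decay gravity measure, a cross-check in the tests.

`classify_zones()` flags zones outside the buffers of *all three*
resource types, and zones strictly below the regional mean logsum for all
three. `equity_summary()` converts flags to household counts; low-income
households are attributed fractionally as
`households * frac_low_income` per zone and rounded half-even once at
table level, since zone-aggregate demographics admit no exact person
count. Default buffer thresholds: a 5-minute walk for parks, a 5-minute
drive for grocery stores, a 10-minute drive for libraries.

## The synthetic region generator

The generator exists because commercial visit-flow data cannot ship with
the package. Its defaults define the package's reference study
conditions: 50 zones on a jittered grid over a 30 km x 12 km extent, with
30 parks, 12 grocery stores, and 8 libraries concentrated toward a
central east-west spine, emulating a linear-corridor county. Households
are lognormal (median 500 per zone); the low-income fraction follows a
logistic curve declining away from the spine (regional mean about 0.16)
plus noise. Park acreage and library floor area are lognormal; amenities
are Bernoulli draws; grocery register counts are shifted Poisson.

Skims are distance-derived: over-the-road distance is Euclidean distance
times a circuity factor of 1.3; driving at 45 km/h plus a 2-minute
terminal time; walking at 4.8 km/h, available within the 10 km walking
limit; transit only when both endpoints lie within 2 km of the spine,
with in-vehicle time along the spine at 30 km/h, wait equal to half a
15-minute headway, access/egress walking from the perpendicular offsets,
and a 2-hour total-time cap. Flows draw each device trip's origin
proportional to households and its destination from the full-choice-set
MNL at the ground-truth coefficients — deliberately mirroring the
estimation-versus-reality structure, since estimation then uses sampled
alternatives. The ground truth defaults to the published
full-specification estimates per resource type, so recovery targets
field-realistic magnitudes.

Two sample sizes deserve explanation. The estimation sample is 10,000
trips with 10 sampled alternatives, matching the reference application.
The flow table behind it is generated from 100,000 device trips per
resource type: commercial location-based-services counts are far larger
than the estimation sample drawn from them, and if the flow table held
only as many trips as are resampled from it, the shared flow-table noise
would inflate estimator variance beyond what the model's own information
matrix describes. One global seed expands into per-stage child seeds by
fixed offsets, so every stage is independently reproducible.

What the generator does *not* emulate: street networks (distances are
circuity-scaled Euclidean, so generated auto times satisfy the triangle
inequality up to terminal-time slack, which real networks need not);
population-weighted centroids (zone centroids are the origins, as in the
reference methodology — the domain types accept either); device-level
measurement error, home-location inference error, and visit
misattribution in LBS data; demographic calibration to census margins;
and any behavioral heterogeneity across neighborhoods. Passing recovery
tests therefore show the estimator and pipeline are correct under the
model's own assumptions — not that the model describes any particular
region.

## Validation design and problem sizes

The test suite validates each layer against an independent route: the
analytic score against central finite differences (relative $10^{-6}$);
the optimizer against golden-section search on an independently coded
likelihood for one-coefficient instances ($10^{-4}$); the full fit
against `survival::clogit` (conditional logit is the same likelihood);
logsum identities (duplication adds exactly $\ln 2$, constant-shift
relativity, monotonicity); and the sampling stages against binomial and
multinomial error bounds. End-to-end, 20 replicates of the default
region are simulated and refitted: 95% Wald intervals must cover the
ground truth at a rate consistent with nominal (binomial test at
$\alpha = 0.01$) and the median absolute relative bias of the impedance
coefficient must stay under 5%. The replicate count and region size keep
the full suite under a minute of estimation time while leaving the
binomial coverage test enough trials (120 intervals) to have power
against real undercoverage.

## Known limitations

Beyond the generator's idealizations: the package estimates pooled MNL
only (no nested, mixed, or latent-class structures); mode-choice
coefficients are asserted rather than estimated; gravity calibration to
observed trip-length distributions is out of scope; and the logsum
surface inherits whatever misspecification the choice model carries —
its advantage over buffers is in what it *can* express, not a guarantee
of truth.
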