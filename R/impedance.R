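# Mode-choice utilities and the mode-choice logsum (MCLS) impedance.
#
# The MCLS is a continuous multimodal impedance: the logsum over the
# utilities of driving, riding transit, and walking between a zone and a
# resource. Its coefficients are asserted, not estimated; the defaults are
# generic regional mode-choice values.

#' Mode-choice utility coefficients
#'
#' Holds the fixed coefficients of the auto, transit, and walk utility
#' functions that feed the mode-choice logsum impedance. All slope
#' coefficients are disutilities per minute (or per mile for walk distance)
#' and must be nonpositive.
#'
#' The walk-distance term uses two coefficients split at `dist_threshold`
#' miles. Under the default `"literal"` dialect a single coefficient applies
#' to the full distance, selected by the threshold, which produces a utility
#' discontinuity at the threshold; the `"marginal"` dialect applies the
#' short-distance rate up to the threshold and the long-distance rate to the
#' remainder, which is continuous.
#'
#' @param b_time Utility per minute of in-vehicle/over-the-road time
#'   (all modes). Default -0.028.
#' @param asc_transit Transit alternative-specific constant. Default -4.
#' @param b_wait Utility per minute of transit wait/transfer time.
#'   Default -0.056.
#' @param b_access Utility per minute of transit access/egress walking.
#'   Default -0.372.
#' @param asc_walk Walk alternative-specific constant. Default -5.
#' @param b_dist_short Utility per mile of walk distance below the
#'   threshold. Default -1.12.
#' @param b_dist_long Utility per mile of walk distance at or above the
#'   threshold. Default -5.58.
#' @param dist_threshold Walk-distance split in miles. Default 1.5.
#' @param dialect `"literal"` or `"marginal"` (see Details).
#' @return An object of class `mode_coefficients`.
#' @export
#' @examples
#' mode_coefficients()
mode_coefficients <- function(b_time = -0.028,
                              asc_transit = -4,
                              b_wait = -0.056,
                              b_access = -0.372,
                              asc_walk = -5,
                              b_dist_short = -1.12,
                              b_dist_long = -5.58,
                              dist_threshold = 1.5,
                              dialect = c("literal", "marginal")) {
  dialect <- match.arg(dialect)
  slopes <- c(b_time = b_time, b_wait = b_wait, b_access = b_access,
              b_dist_short = b_dist_short, b_dist_long = b_dist_long)
  if (any(slopes > 0)) {
    stop_validation("all mode-choice slope coefficients must be nonpositive")
  }
  if (!is.finite(dist_threshold) || dist_threshold <= 0) {
    stop_validation("dist_threshold must be positive")
  }
  structure(
    list(b_time = b_time, asc_transit = asc_transit, b_wait = b_wait,
         b_access = b_access, asc_walk = asc_walk,
         b_dist_short = b_dist_short, b_dist_long = b_dist_long,
         dist_threshold = dist_threshold, dialect = dialect),
    class = "mode_coefficients"
  )
}

#' @export
print.mode_coefficients <- function(x, ...) {
  cat("Mode-choice utility coefficients (", x$dialect, " walk-distance dialect)\n",
      sep = "")
  cat(sprintf("  auto:    %g * time\n", x$b_time))
  cat(sprintf("  transit: %g %+g*ivtt %+g*wait %+g*access\n",
              x$asc_transit, x$b_time, x$b_wait, x$b_access))
  cat(sprintf("  walk:    %g %+g*time, distance %g/mi below %g mi else %g/mi\n",
              x$asc_walk, x$b_time, x$b_dist_short, x$dist_threshold,
              x$b_dist_long))
  invisible(x)
}

#' Per-mode utilities for zone-resource pairs
#'
#' Computes the auto, transit, and walk utilities for every row of a skim
#' table. A mode that is unavailable for a pair gets `NA` utility (the term
#' is dropped from the logsum, not penalized).
#'
#' @param skims Validated skim tibble ([as_skims()]).
#' @param coeffs A [mode_coefficients()] object.
#' @return Tibble with columns `v_auto`, `v_transit`, `v_walk`, one row per
#'   skim row.
#' @export
mode_utilities <- function(skims, coeffs = mode_coefficients()) {
  stopifnot(inherits(coeffs, "mode_coefficients"))
  skims <- as_skims(skims)
  comp <- skims[skim_value_cols()]
  if (any(vapply(comp, function(v) any(!is.na(v) & v < 0), logical(1)))) {
    stop_validation("travel time/distance components must be nonnegative")
  }
  d <- skims$d_walk
  dist_term <- if (coeffs$dialect == "literal") {
    ifelse(d < coeffs$dist_threshold, coeffs$b_dist_short * d,
           coeffs$b_dist_long * d)
  } else {
    coeffs$b_dist_short * pmin(d, coeffs$dist_threshold) +
      coeffs$b_dist_long * pmax(d - coeffs$dist_threshold, 0)
  }
  tibble::tibble(
    v_auto = ifelse(skims$avail_auto, coeffs$b_time * skims$t_auto, NA_real_),
    v_transit = ifelse(skims$avail_transit,
                       coeffs$asc_transit + coeffs$b_time * skims$t_transit_iv +
                         coeffs$b_wait * skims$wt + coeffs$b_access * skims$at,
                       NA_real_),
    v_walk = ifelse(skims$avail_walk,
                    coeffs$asc_walk + coeffs$b_time * skims$t_walk + dist_term,
                    NA_real_)
  )
}

# Overflow-safe logsum across the columns of a matrix, NA entries dropped.
# Rows with no finite entry return NA.
row_logsumexp <- function(m) {
  mx <- suppressWarnings(apply(m, 1, max, na.rm = TRUE))
  out <- mx + log(rowSums(exp(m - mx), na.rm = TRUE))
  out[!is.finite(mx)] <- NA_real_
  out
}

#' Mode-choice logsum impedance
#'
#' `MCLS = log(exp(V_auto) + exp(V_transit) + exp(V_walk))` over the
#' available modes, computed with max-shift stabilization. The MCLS is
#' nonincreasing in every travel-cost component and never below the best
#' available mode utility. Pairs with no available mode return `NA`
#' (unreachable; callers exclude such alternatives).
#'
#' @inheritParams mode_utilities
#' @return Numeric vector, one value per skim row (`NA` = unreachable).
#' @export
#' @examples
#' sk <- as_skims(data.frame(zone_id = "A", resource_id = "p1",
#'   t_auto = 10, t_transit_iv = 20, wt = 5, at = 10,
#'   t_walk = 60, d_walk = 3))
#' mcls(sk)  # about -0.2797: driving dominates
mcls <- function(skims, coeffs = mode_coefficients()) {
  v <- mode_utilities(skims, coeffs)
  row_logsumexp(as.matrix(v))
}

#' Impedance matrix between zones and resources
#'
#' Evaluates the chosen impedance for every (zone, resource) pair, flagging
#' unreachable pairs. `kind = "t_auto"` / `"t_walk"` pass raw skim minutes
#' through (the single-mode impedances of the simpler model
#' specifications); `kind = "mcls"` evaluates the multimodal logsum.
#'
#' @inheritParams mode_utilities
#' @param kind `"mcls"`, `"t_auto"`, or `"t_walk"`.
#' @return Tibble `zone_id`, `resource_id`, `impedance`, `reachable`.
#' @export
impedance_matrix <- function(skims, coeffs = mode_coefficients(),
                             kind = c("mcls", "t_auto", "t_walk")) {
  kind <- match.arg(kind)
  skims <- as_skims(skims)
  imp <- switch(kind,
    mcls = mcls(skims, coeffs),
    t_auto = ifelse(skims$avail_auto, skims$t_auto, NA_real_),
    t_walk = ifelse(skims$avail_walk, skims$t_walk, NA_real_)
  )
  tibble::tibble(
    zone_id = skims$zone_id,
    resource_id = skims$resource_id,
    impedance = imp,
    reachable = !is.na(imp)
  )
}
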