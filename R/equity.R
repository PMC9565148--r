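# Household-weighted equity accounting: which zones (and how many
# households, and how many low-income households) have low access under
# the buffer definition, under the logsum definition, and under both.

#' Classify zones by access status across all resource types
#'
#' A zone is `outside_all_buffers` when its binary buffer flag is 0 for
#' every resource type, and `below_mean_all_logsum` when its logsum access
#' is strictly below the regional mean for every resource type.
#'
#' @param buffers Named list of binary buffer surfaces, one per resource
#'   type (names `park`, `grocery`, `library`).
#' @param logsums Named list of logsum surfaces, same names.
#' @param zones Zone tibble.
#' @param weight_households Household-weight the regional mean logsum
#'   (default unweighted).
#' @return Tibble `zone_id`, `outside_all_buffers`, `below_mean_all_logsum`.
#' @export
classify_zones <- function(buffers, logsums, zones,
                           weight_households = FALSE) {
  zones <- as_zones(zones)
  need <- resource_types()
  if (!all(need %in% names(buffers)) || !all(need %in% names(logsums))) {
    stop_validation(sprintf("buffers and logsums must both cover: %s",
                            paste(need, collapse = ", ")))
  }
  out <- tibble::tibble(zone_id = zones$zone_id,
                        outside_all_buffers = TRUE,
                        below_mean_all_logsum = TRUE)
  for (rt in need) {
    b <- buffers[[rt]]
    l <- logsums[[rt]]
    ib <- match(out$zone_id, b$zone_id)
    il <- match(out$zone_id, l$zone_id)
    if (any(is.na(ib)) || any(is.na(il))) {
      stop_validation(sprintf("surface for %s does not cover every zone", rt))
    }
    out$outside_all_buffers <- out$outside_all_buffers & (b$value[ib] == 0)
    ok <- !is.na(l$value)
    w <- if (weight_households) zones$households[match(l$zone_id, zones$zone_id)] else
      rep(1, nrow(l))
    mu <- sum(w[ok] * l$value[ok]) / sum(w[ok])
    below <- !is.na(l$value[il]) & l$value[il] < mu
    out$below_mean_all_logsum <- out$below_mean_all_logsum & below
  }
  out
}

#' Household counts by low-access classification
#'
#' Sums zone households over the flagged zones, under the buffer
#' definition, the logsum definition, and their overlap. Low-income
#' households are attributed fractionally as
#' `households * frac_low_income` per zone and rounded half-even once at
#' table level.
#'
#' @param flags Output of [classify_zones()].
#' @param zones Zone tibble.
#' @return One-row tibble of class `equity_table`: `hh_outside_buffers`,
#'   `low_inc_outside_buffers`, `hh_below_mean_logsum`,
#'   `low_inc_below_mean_logsum`, `hh_both`, `low_inc_both`.
#' @export
equity_summary <- function(flags, zones) {
  zones <- as_zones(zones)
  df <- dplyr::left_join(flags, zones[c("zone_id", "households", "frac_low_income")],
                         by = "zone_id")
  hh <- function(sel) sum(df$households[sel])
  li <- function(sel) round(sum(df$households[sel] * df$frac_low_income[sel]))
  both <- df$outside_all_buffers & df$below_mean_all_logsum
  out <- tibble::tibble(
    hh_outside_buffers = hh(df$outside_all_buffers),
    low_inc_outside_buffers = li(df$outside_all_buffers),
    hh_below_mean_logsum = hh(df$below_mean_all_logsum),
    low_inc_below_mean_logsum = li(df$below_mean_all_logsum),
    hh_both = hh(both),
    low_inc_both = li(both)
  )
  structure(out, class = c("equity_table", class(out)))
}

#' @export
print.equity_table <- function(x, ...) {
  cat(format_equity(x), sep = "\n")
  invisible(x)
}

#' Narrative text block for an equity table
#'
#' @param x An `equity_table`.
#' @return Character vector of lines.
#' @export
format_equity <- function(x) {
  c(sprintf("%d households live in zones outside the buffers of all three resources (%d low-income).",
            x$hh_outside_buffers, x$low_inc_outside_buffers),
    sprintf("%d households live in zones below the regional mean utility-based access to all three resources (%d low-income).",
            x$hh_below_mean_logsum, x$low_inc_below_mean_logsum),
    sprintf("%d households are in both low-access groups (%d low-income).",
            x$hh_both, x$low_inc_both))
}

#' @rdname format_equity
#' @param path Output CSV path.
#' @export
write_equity <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}
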