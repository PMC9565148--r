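#' @importFrom rlang .data abort warn
#' @importFrom stats optimize pnorm rbinom rlnorm rmultinom rnorm rpois runif
#'   plogis setNames var sd median qnorm
#' @importFrom utils modifyList
NULL

#' Resource types understood by the package
#'
#' Community resources carry a type-specific attribute schema: parks have a
#' size in acres and sports/play amenities, grocery stores have register
#' counts and store-format flags, libraries have floor area and program
#' flags. Size fields must be strictly positive because the default model
#' specifications enter them in logs.
#'
#' @return Character vector of supported resource types.
#' @export
resource_types <- function() c("park", "grocery", "library")

#' Attribute schema for a resource type
#'
#' @param rtype One of `resource_types()`.
#' @return A tibble with columns `attribute` and `kind`
#'   (`"size"`, `"count"`, or `"flag"`).
#' @export
#' @examples
#' resource_schema("park")
resource_schema <- function(rtype) {
  rtype <- match.arg(rtype, resource_types())
  switch(rtype,
    park = tibble::tibble(
      attribute = c("acres", "playground", "volleyball", "basketball", "tennis"),
      kind = c("size", "flag", "flag", "flag", "flag")
    ),
    grocery = tibble::tibble(
      attribute = c("n_registers", "n_selfcheckout", "convenience",
                    "other_nonstandard", "pharmacy", "ethnic_market",
                    "other_merchandise"),
      kind = c("count", "count", rep("flag", 5))
    ),
    library = tibble::tibble(
      attribute = c("sqft", "offers_classes", "genealogy"),
      kind = c("size", "flag", "flag")
    )
  )
}

stop_schema <- function(msg) abort(msg, class = "utilaccess_schema_error")
stop_validation <- function(msg) abort(msg, class = "utilaccess_validation_error")

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_schema(sprintf("%s is missing required column(s): %s",
                        what, paste(missing, collapse = ", ")))
  }
}

#' Validate and construct a zone table
#'
#' Zones are the origin neighborhoods of the analysis (census block groups in
#' a typical application). Each zone has a planar centroid, a household
#' count, and the fraction of households that are low-income. Coordinates
#' are taken as already-projected planar units (km); the package performs no
#' coordinate transformation.
#'
#' @param df A data frame with columns `zone_id`, `x`, `y`, `households`,
#'   `frac_low_income`. Extra columns (e.g., further demographics) are
#'   carried through untouched.
#' @return A validated tibble of zones.
#' @export
as_zones <- function(df) {
  df <- tibble::as_tibble(df)
  require_columns(df, c("zone_id", "x", "y", "households", "frac_low_income"),
                  "zone table")
  df$zone_id <- as.character(df$zone_id)
  if (anyDuplicated(df$zone_id)) {
    stop_validation("duplicate zone_id in zone table")
  }
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    stop_validation("zone centroids must be finite")
  }
  if (any(is.na(df$households)) || any(df$households < 0)) {
    stop_schema("households must be nonnegative")
  }
  if (any(is.na(df$frac_low_income)) ||
      any(df$frac_low_income < 0 | df$frac_low_income > 1)) {
    stop_schema("frac_low_income must lie in [0, 1]")
  }
  df
}

coerce_flag <- function(x, name) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1, NA))) {
      stop_schema(sprintf("column %s must be 0/1 or logical", name))
    }
    return(x == 1)
  }
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lx %in% c("1", "true", "t", "yes")] <- TRUE
  out[lx %in% c("0", "false", "f", "no")] <- FALSE
  if (any(is.na(out) & !is.na(x))) {
    stop_schema(sprintf("column %s has values not coercible to logical", name))
  }
  out
}

#' Validate and construct a resource table
#'
#' @param df Data frame with `resource_id`, `x`, `y`, and the attribute
#'   columns of the type's schema (see [resource_schema()]). Boolean
#'   attributes are coerced from 0/1 or true/false. Unknown columns are
#'   carried through but are not usable in a model specification unless
#'   declared there.
#' @param rtype One of `resource_types()`.
#' @return A validated tibble of resources with an `rtype` column.
#' @export
as_resources <- function(df, rtype) {
  rtype <- match.arg(rtype, resource_types())
  df <- tibble::as_tibble(df)
  schema <- resource_schema(rtype)
  require_columns(df, c("resource_id", "x", "y", schema$attribute),
                  sprintf("%s resource table", rtype))
  df$resource_id <- as.character(df$resource_id)
  if (anyDuplicated(df$resource_id)) {
    stop_validation("duplicate resource_id in resource table")
  }
  for (i in seq_len(nrow(schema))) {
    a <- schema$attribute[i]
    if (schema$kind[i] == "flag") {
      df[[a]] <- coerce_flag(df[[a]], a)
    } else {
      df[[a]] <- as.numeric(df[[a]])
      if (any(is.na(df[[a]]))) stop_schema(sprintf("column %s has missing values", a))
      if (schema$kind[i] == "size" && any(df[[a]] <= 0)) {
        stop_validation(sprintf(
          "size attribute %s must be strictly positive (it is log-transformed downstream)", a))
      }
      if (schema$kind[i] == "count" && any(df[[a]] < 0)) {
        stop_validation(sprintf("count attribute %s must be nonnegative", a))
      }
    }
  }
  df$rtype <- rtype
  dplyr::relocate(df, "resource_id", "rtype", "x", "y")
}

skim_value_cols <- function() {
  c("t_auto", "t_transit_iv", "wt", "at", "t_walk", "d_walk")
}

#' Validate and construct a travel skim table
#'
#' A skim holds per-mode travel-cost components for zone-resource pairs:
#' auto time, transit in-vehicle / wait / access-egress times, walk time,
#' and walk distance, with per-mode availability flags. A missing component
#' encodes mode unavailability for that pair, never zero cost; availability
#' flags are forced consistent with the missingness pattern.
#'
#' @param df Data frame keyed by (`zone_id`, `resource_id`) with time
#'   components in minutes and `d_walk` in miles. Optional logical columns
#'   `avail_auto`, `avail_transit`, `avail_walk`; when absent they are
#'   derived from missingness.
#' @return Validated skim tibble with availability flags.
#' @export
as_skims <- function(df) {
  df <- tibble::as_tibble(df)
  require_columns(df, c("zone_id", "resource_id", skim_value_cols()), "skim table")
  df$zone_id <- as.character(df$zone_id)
  df$resource_id <- as.character(df$resource_id)
  if (anyDuplicated(df[c("zone_id", "resource_id")])) {
    stop_validation("duplicate (zone_id, resource_id) pair in skim table")
  }
  for (col in skim_value_cols()) df[[col]] <- as.numeric(df[[col]])

  a_auto <- if ("avail_auto" %in% names(df)) coerce_flag(df$avail_auto, "avail_auto") else
    !is.na(df$t_auto)
  a_tr <- if ("avail_transit" %in% names(df)) coerce_flag(df$avail_transit, "avail_transit") else
    !(is.na(df$t_transit_iv) | is.na(df$wt) | is.na(df$at))
  a_wk <- if ("avail_walk" %in% names(df)) coerce_flag(df$avail_walk, "avail_walk") else
    !(is.na(df$t_walk) | is.na(df$d_walk))
  a_auto <- a_auto & !is.na(df$t_auto)
  a_tr <- a_tr & !(is.na(df$t_transit_iv) | is.na(df$wt) | is.na(df$at))
  a_wk <- a_wk & !(is.na(df$t_walk) | is.na(df$d_walk))
  # unavailable modes carry no cost information
  df$t_auto[!a_auto] <- NA_real_
  df$t_transit_iv[!a_tr] <- NA_real_
  df$wt[!a_tr] <- NA_real_
  df$at[!a_tr] <- NA_real_
  df$t_walk[!a_wk] <- NA_real_
  df$d_walk[!a_wk] <- NA_real_
  df$avail_auto <- a_auto
  df$avail_transit <- a_tr
  df$avail_walk <- a_wk

  for (col in skim_value_cols()) {
    bad <- !is.na(df[[col]]) & df[[col]] < 0
    if (any(bad)) stop_validation(sprintf("skim component %s has negative values", col))
  }
  df
}

#' Validate and construct a visit-flow table
#'
#' Visit flows are device-trip counts between residence zones and resources,
#' as aggregated from location-based-services data (or simulated by
#' [gen_flows()]).
#'
#' @param df Data frame with `zone_id`, `resource_id`, `count`.
#' @param zones,resources Optional tables; when given, flow ids must resolve
#'   against them.
#' @return Validated flow tibble.
#' @export
as_flows <- function(df, zones = NULL, resources = NULL) {
  df <- tibble::as_tibble(df)
  require_columns(df, c("zone_id", "resource_id", "count"), "flow table")
  df$zone_id <- as.character(df$zone_id)
  df$resource_id <- as.character(df$resource_id)
  df$count <- as.numeric(df$count)
  if (any(is.na(df$count)) || any(df$count < 0) ||
      any(df$count != round(df$count))) {
    stop_validation("flow counts must be nonnegative integers")
  }
  if (!is.null(zones) && !all(df$zone_id %in% zones$zone_id)) {
    stop_validation("flow table references unknown zone_id")
  }
  if (!is.null(resources) && !all(df$resource_id %in% resources$resource_id)) {
    stop_validation("flow table references unknown resource_id")
  }
  df
}

read_table_auto <- function(path, format) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE))
      "geojson" else "csv"
  }
  if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    read_geojson_table(path)
  }
}

# Minimal GeoJSON FeatureCollection reader: properties become columns; when
# x/y are not among the properties they are filled with the geometric
# centroid of the feature (Point, Polygon outer ring by the shoelace
# formula, or area-weighted MultiPolygon).
read_geojson_table <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop_schema("GeoJSON input must be a FeatureCollection")
  }
  rows <- purrr::map(gj$features, function(f) {
    props <- purrr::map(f$properties, function(v) if (is.null(v)) NA else v)
    if (!all(c("x", "y") %in% names(props))) {
      cen <- geojson_centroid(f$geometry)
      props$x <- cen[1]
      props$y <- cen[2]
    }
    tibble::as_tibble(props)
  })
  dplyr::bind_rows(rows)
}

ring_area_centroid <- function(ring) {
  xy <- do.call(rbind, purrr::map(ring, ~ c(.x[[1]], .x[[2]])))
  n <- nrow(xy)
  i <- seq_len(n - 1)
  cross <- xy[i, 1] * xy[i + 1, 2] - xy[i + 1, 1] * xy[i, 2]
  area <- sum(cross) / 2
  if (abs(area) < 1e-12) {
    return(list(area = 0, centroid = colMeans(xy[seq_len(n - 1), , drop = FALSE])))
  }
  cx <- sum((xy[i, 1] + xy[i + 1, 1]) * cross) / (6 * area)
  cy <- sum((xy[i, 2] + xy[i + 1, 2]) * cross) / (6 * area)
  list(area = area, centroid = c(cx, cy))
}

geojson_centroid <- function(geom) {
  if (is.null(geom$type)) stop_schema("feature has no geometry")
  switch(geom$type,
    Point = c(geom$coordinates[[1]], geom$coordinates[[2]]),
    Polygon = ring_area_centroid(geom$coordinates[[1]])$centroid,
    MultiPolygon = {
      parts <- purrr::map(geom$coordinates, ~ ring_area_centroid(.x[[1]]))
      w <- abs(purrr::map_dbl(parts, "area"))
      cen <- do.call(rbind, purrr::map(parts, "centroid"))
      if (sum(w) == 0) colMeans(cen) else colSums(cen * w) / sum(w)
    },
    stop_schema(sprintf("unsupported geometry type: %s", geom$type))
  )
}

#' Read zones from CSV or GeoJSON
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, or `"geojson"`.
#' @return Validated zone tibble (see [as_zones()]).
#' @export
read_zones <- function(path, format = c("auto", "csv", "geojson")) {
  as_zones(read_table_auto(path, match.arg(format)))
}

#' Read resources of one type from CSV or GeoJSON
#'
#' @inheritParams read_zones
#' @param rtype One of `resource_types()`.
#' @return Validated resource tibble (see [as_resources()]).
#' @export
read_resources <- function(path, rtype, format = c("auto", "csv", "geojson")) {
  as_resources(read_table_auto(path, match.arg(format)), rtype)
}

#' Read or write a skim table
#'
#' The on-disk format is a long CSV keyed by (`zone_id`, `resource_id`) with
#' columns `t_auto`, `t_transit_iv`, `wt`, `at`, `t_walk`, `d_walk`; a blank
#' field means the component (and hence the mode) is unavailable for that
#' pair. Write followed by read is the identity on values and availability.
#'
#' @param path File path.
#' @param zones,resources Optional tables for id resolution; when given,
#'   every pair in the file must reference known ids.
#' @return `read_skims()` returns a validated skim tibble.
#' @export
read_skims <- function(path, zones = NULL, resources = NULL) {
  sk <- as_skims(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
  if (!is.null(zones) && !all(sk$zone_id %in% zones$zone_id)) {
    stop_validation("skim table references unknown zone_id")
  }
  if (!is.null(resources) && !all(sk$resource_id %in% resources$resource_id)) {
    stop_validation("skim table references unknown resource_id")
  }
  sk
}

#' @rdname read_skims
#' @param skims A validated skim tibble.
#' @export
write_skims <- function(skims, path) {
  out <- as_skims(skims)[c("zone_id", "resource_id", skim_value_cols())]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read or write a visit-flow table
#'
#' @inheritParams read_skims
#' @param flows A validated flow tibble.
#' @return `read_flows()` returns a validated flow tibble.
#' @export
read_flows <- function(path, zones = NULL, resources = NULL) {
  as_flows(readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
           zones, resources)
}

#' @rdname read_flows
#' @export
write_flows <- function(flows, path) {
  readr::write_csv(as_flows(flows), path)
  invisible(path)
}

#' Write zones or resources to CSV
#'
#' @param x A zone or resource tibble.
#' @param path File path.
#' @export
write_zones <- function(x, path) {
  readr::write_csv(as_zones(x), path)
  invisible(path)
}

#' @rdname write_zones
#' @param rtype Resource type for validation.
#' @export
write_resources <- function(x, path, rtype) {
  readr::write_csv(as_resources(x, rtype), path)
  invisible(path)
}

unavailable_skim_row <- function(zone_id, resource_id) {
  tibble::tibble(
    zone_id = zone_id, resource_id = resource_id,
    t_auto = NA_real_, t_transit_iv = NA_real_, wt = NA_real_, at = NA_real_,
    t_walk = NA_real_, d_walk = NA_real_,
    avail_auto = FALSE, avail_transit = FALSE, avail_walk = FALSE
  )
}

#' Total lookup of a zone-resource pair in a skim table
#'
#' Lookup never silently defaults: a pair absent from the table is reported
#' as fully unavailable (all modes unavailable, all components missing).
#'
#' @param skims Validated skim tibble.
#' @param zone_id,resource_id Ids of the pair.
#' @return One-row skim tibble.
#' @export
skim_lookup <- function(skims, zone_id, resource_id) {
  hit <- skims[skims$zone_id == zone_id & skims$resource_id == resource_id, ]
  if (nrow(hit) == 0) {
    return(unavailable_skim_row(as.character(zone_id), as.character(resource_id)))
  }
  hit
}

# Expand a skim table to the full zone x resource cross, marking absent
# pairs fully unavailable. Keeps every downstream lookup total.
complete_skims <- function(skims, zones, resources) {
  full <- tidyr::expand_grid(zone_id = zones$zone_id,
                             resource_id = resources$resource_id)
  out <- dplyr::left_join(full, skims, by = c("zone_id", "resource_id"))
  for (fl in c("avail_auto", "avail_transit", "avail_walk")) {
    out[[fl]][is.na(out[[fl]])] <- FALSE
  }
  out
}
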