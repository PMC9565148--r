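# Per-zone accessibility surfaces: the utility-based logsum measure, the
# travel-time buffer / cumulative-opportunity measure, and the gravity
# measure, plus their alignment for comparison.

new_access_surface <- function(df, measure, rtype, metadata = list()) {
  structure(tibble::as_tibble(df),
            measure = measure, rtype = rtype, metadata = metadata,
            class = c("access_surface", class(tibble::tibble())))
}

#' @export
print.access_surface <- function(x, ...) {
  meta <- attr(x, "metadata")
  cat(sprintf("Access surface: %s (%s), %d zones\n",
              attr(x, "measure"), attr(x, "rtype"), nrow(x)))
  if (attr(x, "measure") == "logsum") {
    cat("  relative measure: only differences between zones are meaningful\n")
  }
  if (length(meta) > 0) {
    cat("  ", paste(names(meta), unlist(lapply(meta, format)), sep = "=",
                    collapse = ", "), "\n", sep = "")
  }
  NextMethod()
}

resolve_model_coef <- function(model, spec) {
  if (inherits(model, "choice_model")) {
    if (is.null(spec)) spec <- model$spec
    return(list(coef = model$coef, spec = spec))
  }
  if (is.numeric(model) && !is.null(names(model))) {
    if (is.null(spec)) stop_validation("spec is required when model is a coefficient vector")
    return(list(coef = model, spec = spec))
  }
  stop_validation("model must be a choice_model or a named coefficient vector")
}

#' Utility-based (logsum) accessibility surface
#'
#' For each zone, the log of the summed exponentiated destination utilities
#' over the FULL resource inventory of the type:
#' `A_i = log sum_j exp(beta * impedance_ij + X_j gamma)`. Unreachable
#' pairs are excluded from the sum; a zone with no reachable resource gets
#' `NA` and is excluded from means. The measure is relative (the unknown
#' constant is fixed at zero): only differences between zones carry
#' meaning. `standardize` subtracts the regional mean, optionally
#' household-weighted.
#'
#' @param model A fitted [mnl_fit()] model or a named coefficient vector
#'   (with `spec` supplied).
#' @param zones,resources,skims Region tables.
#' @param coeffs [mode_coefficients()] for the impedance evaluation.
#' @param spec Override the model's [model_spec()].
#' @param standardize Subtract the regional mean access.
#' @param weight_households Household-weight the regional mean.
#' @return An `access_surface` tibble: `zone_id`, `value`, `reachable`.
#' @export
logsum_access <- function(model, zones, resources, skims,
                          coeffs = mode_coefficients(), spec = NULL,
                          standardize = FALSE, weight_households = FALSE) {
  mc <- resolve_model_coef(model, spec)
  spec <- mc$spec
  covars <- covariate_names(spec)
  if (!all(covars %in% names(mc$coef))) {
    stop_validation("model coefficients do not cover the spec's covariates")
  }
  zones <- as_zones(zones)
  sk <- complete_skims(as_skims(skims), zones, resources)
  imp <- impedance_matrix(sk, coeffs, kind = spec$impedance)

  attrs <- resources[c("resource_id", spec$terms$attribute)]
  for (i in seq_len(nrow(spec$terms))) {
    a <- spec$terms$attribute[i]
    v <- as.numeric(attrs[[a]])
    attrs[[a]] <- if (spec$terms$transform[i] == "log") log(v) else v
  }
  names(attrs) <- c("resource_id", covars[-1])
  long <- dplyr::left_join(imp, attrs, by = "resource_id")
  names(long)[names(long) == "impedance"] <- covars[1]
  X <- as.matrix(long[covars])
  v <- drop(X %*% mc$coef[covars])
  v[!long$reachable] <- NA_real_

  vm <- matrix(v, nrow = nrow(zones), byrow = TRUE)  # zones x resources order
  # impedance_matrix preserved expand_grid order: zone-major
  val <- row_logsumexp(vm)
  out <- tibble::tibble(zone_id = zones$zone_id, value = val,
                        reachable = !is.na(val))
  if (standardize) {
    w <- if (weight_households) zones$households else rep(1, nrow(zones))
    ok <- out$reachable
    mu <- sum(w[ok] * out$value[ok]) / sum(w[ok])
    out$value <- out$value - mu
  }
  new_access_surface(out, "logsum", spec$rtype,
                     list(impedance = spec$impedance,
                          standardized = standardize,
                          weighted = weight_households))
}

mode_time_col <- function(mode) {
  switch(mode, auto = c("t_auto", "avail_auto"),
         walk = c("t_walk", "avail_walk"),
         stop_schema(sprintf("no travel-time column for mode '%s'", mode)))
}

#' Nearest-resource travel time per zone
#'
#' @param zones,resources,skims Region tables.
#' @param mode `"auto"` or `"walk"`.
#' @return Tibble `zone_id`, `nearest_time` (`Inf` when no resource is
#'   reachable by the mode).
#' @export
nearest_time <- function(zones, resources, skims, mode = c("auto", "walk")) {
  mode <- match.arg(mode)
  cols <- mode_time_col(mode)
  sk <- complete_skims(as_skims(skims), as_zones(zones), resources)
  t <- ifelse(sk[[cols[2]]], sk[[cols[1]]], NA_real_)
  tm <- matrix(t, nrow = nrow(zones), byrow = TRUE)
  tibble::tibble(
    zone_id = zones$zone_id,
    nearest_time = apply(tm, 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r) == 0) Inf else min(r)
    })
  )
}

#' Travel-time buffer / cumulative-opportunity accessibility
#'
#' Binary form: a zone has access (value 1) iff any resource lies within
#' `t_star` minutes by the given mode (closed inequality `t <= t_star`).
#' Cumulative form: the count of resources within the threshold.
#'
#' @inheritParams nearest_time
#' @param t_star Travel-time threshold in minutes (> 0).
#' @param cumulative Count resources instead of the binary indicator.
#' @return An `access_surface` tibble.
#' @export
buffer_access <- function(zones, resources, skims, mode = c("auto", "walk"),
                          t_star, cumulative = FALSE) {
  mode <- match.arg(mode)
  if (!is.finite(t_star) || t_star <= 0) stop_validation("t_star must be positive")
  cols <- mode_time_col(mode)
  zones <- as_zones(zones)
  sk <- complete_skims(as_skims(skims), zones, resources)
  inside <- sk[[cols[2]]] & !is.na(sk[[cols[1]]]) & sk[[cols[1]]] <= t_star
  m <- matrix(inside, nrow = nrow(zones), byrow = TRUE)
  val <- if (cumulative) rowSums(m) else as.numeric(rowSums(m) > 0)
  rt <- unique(resources$rtype)
  new_access_surface(
    tibble::tibble(zone_id = zones$zone_id, value = val),
    if (cumulative) "cumulative" else "buffer",
    if (length(rt) == 1) rt else "mixed",
    list(mode = mode, t_star = t_star)
  )
}

#' Gravity accessibility
#'
#' `A_i = sum_j S_j f(t_ij, beta)` with `S_j` a positive size attribute of
#' the resource (1 when `size_attr` is `NULL`) and `f` a continuous decay:
#' exponential `exp(-beta t)` or power `t^-beta` with travel time floored
#' at one minute.
#'
#' @inheritParams nearest_time
#' @param size_attr Name of a positive resource attribute, or `NULL`.
#' @param decay `"exponential"` or `"power"`.
#' @param beta Positive decay parameter.
#' @return An `access_surface` tibble.
#' @export
gravity_access <- function(zones, resources, skims, size_attr = NULL,
                           decay = c("exponential", "power"), beta,
                           mode = c("auto", "walk")) {
  decay <- match.arg(decay)
  mode <- match.arg(mode)
  if (!is.finite(beta) || beta <= 0) stop_validation("decay parameter beta must be > 0")
  cols <- mode_time_col(mode)
  zones <- as_zones(zones)
  S <- if (is.null(size_attr)) rep(1, nrow(resources)) else {
    v <- as.numeric(resources[[size_attr]])
    if (any(is.na(v) | v <= 0)) stop_validation("size attribute must be positive")
    v
  }
  sk <- complete_skims(as_skims(skims), zones, resources)
  t <- ifelse(sk[[cols[2]]], sk[[cols[1]]], NA_real_)
  f <- switch(decay,
              exponential = exp(-beta * t),
              power = pmax(t, 1)^(-beta))
  contrib <- matrix(f * rep(S, times = nrow(zones)), nrow = nrow(zones),
                    byrow = TRUE)
  rt <- unique(resources$rtype)
  new_access_surface(
    tibble::tibble(zone_id = zones$zone_id,
                   value = rowSums(contrib, na.rm = TRUE)),
    "gravity", if (length(rt) == 1) rt else "mixed",
    list(decay = decay, beta = beta, size_attr = size_attr %||% "1",
         mode = mode)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align a buffer surface and a logsum surface for comparison
#'
#' Joins, per zone, the nearest-resource travel time (by the buffer's
#' mode), the binary buffer flag, and the logsum value, and summarizes the
#' dispersion of the logsum within travel-time bands. Zones at equal
#' nearest travel time can hold very different logsum access when resource
#' quality or multimodal options differ -- dispersion the binary buffer
#' cannot express.
#'
#' @param buffer A binary `buffer` access surface.
#' @param logsum A `logsum` access surface on the same zones and type.
#' @param zones,resources,skims Region tables (for nearest times).
#' @param band_width Width of the travel-time bands, minutes.
#' @return An `access_comparison` tibble (`zone_id`, `nearest_time`,
#'   `buffer`, `logsum`) with a `bands` attribute summarizing within-band
#'   logsum variance.
#' @export
compare_surfaces <- function(buffer, logsum, zones, resources, skims,
                             band_width = 2) {
  if (attr(buffer, "measure") != "buffer" || attr(logsum, "measure") != "logsum") {
    stop_validation("compare_surfaces expects a buffer surface and a logsum surface")
  }
  if (nrow(resources) == 0) stop_validation("empty resource set")
  if (!setequal(buffer$zone_id, logsum$zone_id) ||
      nrow(buffer) != nrow(logsum)) {
    stop_validation("surfaces cover different zone sets")
  }
  if (attr(buffer, "rtype") != attr(logsum, "rtype")) {
    stop_validation("surfaces describe different resource types")
  }
  mode <- attr(buffer, "metadata")$mode
  nt <- nearest_time(zones, resources, skims, mode = mode)
  out <- dplyr::left_join(nt, tibble::tibble(zone_id = buffer$zone_id,
                                             buffer = buffer$value),
                          by = "zone_id")
  out <- dplyr::left_join(out, tibble::tibble(zone_id = logsum$zone_id,
                                              logsum = logsum$value),
                          by = "zone_id")
  t_star <- attr(buffer, "metadata")$t_star
  fin <- is.finite(out$nearest_time) & !is.na(out$logsum)
  band <- floor(out$nearest_time[fin] / band_width)
  bands <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(
      band_lo = band * band_width,
      band_hi = (band + 1) * band_width,
      logsum = out$logsum[fin],
      buffer = out$buffer[fin]
    ), .data$band_lo, .data$band_hi),
    n = dplyr::n(),
    mean_logsum = mean(.data$logsum),
    var_logsum = if (dplyr::n() > 1) var(.data$logsum) else NA_real_,
    buffer_constant = dplyr::n_distinct(.data$buffer) == 1,
    .groups = "drop"
  )
  bands$straddles_threshold <- bands$band_lo < t_star & t_star < bands$band_hi
  structure(out, bands = bands, t_star = t_star, mode = mode,
            rtype = attr(buffer, "rtype"),
            class = c("access_comparison", class(out)))
}

#' @export
print.access_comparison <- function(x, ...) {
  cat(sprintf("Buffer vs logsum comparison (%s, %s mode, t* = %g min)\n",
              attr(x, "rtype"), attr(x, "mode"), attr(x, "t_star")))
  NextMethod()
  cat("\nLogsum dispersion within travel-time bands:\n")
  print(attr(x, "bands"))
  invisible(x)
}

#' Scatter of logsum access against nearest travel time
#'
#' The characteristic comparison figure: logsum access against the
#' nearest-resource travel time, with the buffer threshold as a dashed
#' line. Vertical spread at fixed travel time is what the binary buffer
#' measure cannot represent.
#'
#' @param cmp An `access_comparison` from [compare_surfaces()].
#' @return A ggplot object.
#' @export
plot_access_comparison <- function(cmp) {
  df <- tibble::as_tibble(cmp)
  df <- df[is.finite(df$nearest_time), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nearest_time, y = .data$logsum,
                                   colour = factor(.data$buffer))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = attr(cmp, "t_star"), linetype = "dashed") +
    ggplot2::labs(x = sprintf("Nearest-resource travel time (%s, min)", attr(cmp, "mode")),
                  y = "Logsum access (relative utils)",
                  colour = "In buffer") +
    ggplot2::theme_minimal()
}

#' Write an access surface to CSV (optionally GeoJSON-joinable)
#'
#' @param surface An `access_surface`.
#' @param path Output CSV path.
#' @export
write_surface <- function(surface, path) {
  df <- tibble::as_tibble(surface)
  df$measure <- attr(surface, "measure")
  readr::write_csv(df[c("zone_id", "measure", "value")], path)
  invisible(path)
}
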