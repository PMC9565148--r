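# Assembly of the destination-choice estimation dataset: sample chosen
# trips from the visit-flow table, pair each with random non-chosen
# alternatives, and attach impedance and destination-attribute covariates.

#' Destination-choice model specification
#'
#' Declares the covariates of a destination utility function: the impedance
#' term (multimodal logsum or raw drive time) plus destination attribute
#' terms, each with an optional log transform. The defaults reproduce the
#' full "impedance + all attributes" specification for each resource type,
#' with size attributes (park acres, library square footage) entered in
#' logs.
#'
#' @param rtype One of `resource_types()`.
#' @param impedance `"mcls"` or `"t_auto"`.
#' @param terms Tibble with columns `attribute` and `transform`
#'   (`"identity"` or `"log"`); default is the full attribute set of the
#'   type's schema. Log transforms are only allowed on strictly positive
#'   attributes.
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("park")
#' model_spec("grocery", impedance = "t_auto")
model_spec <- function(rtype, impedance = c("mcls", "t_auto"), terms = NULL) {
  rtype <- match.arg(rtype, resource_types())
  impedance <- match.arg(impedance)
  schema <- resource_schema(rtype)
  if (is.null(terms)) {
    terms <- tibble::tibble(
      attribute = schema$attribute,
      transform = ifelse(schema$kind == "size", "log", "identity")
    )
  }
  terms <- tibble::as_tibble(terms)
  require_columns(terms, c("attribute", "transform"), "model_spec terms")
  unknown <- setdiff(terms$attribute, schema$attribute)
  if (length(unknown) > 0) {
    stop_schema(sprintf("attribute(s) not in the %s schema: %s",
                        rtype, paste(unknown, collapse = ", ")))
  }
  if (!all(terms$transform %in% c("identity", "log"))) {
    stop_schema("transform must be 'identity' or 'log'")
  }
  bad_log <- terms$transform == "log" &
    schema$kind[match(terms$attribute, schema$attribute)] != "size"
  if (any(bad_log)) {
    stop_schema("log transform is only allowed on strictly positive size attributes")
  }
  structure(list(rtype = rtype, impedance = impedance, terms = terms),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Destination choice spec (%s): impedance = %s\n",
              x$rtype, x$impedance))
  cat("  terms:", paste(covariate_names(x)[-1], collapse = ", "), "\n")
  invisible(x)
}

#' Covariate column names implied by a model specification
#'
#' The impedance column is named after its kind; log-transformed attributes
#' are prefixed `log_`.
#'
#' @param spec A [model_spec()] object.
#' @return Character vector (impedance first).
#' @export
covariate_names <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  attr_names <- ifelse(spec$terms$transform == "log",
                       paste0("log_", spec$terms$attribute),
                       spec$terms$attribute)
  c(spec$impedance, attr_names)
}

#' Sample chosen trips from a visit-flow table
#'
#' Draws `n_trips` (zone, resource) trips i.i.d. with probability
#' proportional to the flow counts, emulating the sampling of observed
#' device trips from an aggregated location-based-services table.
#'
#' @param flows Validated flow tibble.
#' @param n_trips Number of trips to draw (default 10000).
#' @param seed Integer seed (mandatory; the draw is reproducible).
#' @return Tibble `obs_id`, `zone_id`, `resource_id` (the chosen resource).
#' @export
sample_trips <- function(flows, n_trips = 10000, seed) {
  flows <- as_flows(flows)
  if (missing(seed)) stop_validation("seed is required for sample_trips")
  pos <- flows[flows$count > 0, ]
  if (nrow(pos) == 0) stop_validation("all flow counts are zero; nothing to sample")
  idx <- withr::with_seed(as.integer(seed),
    sample.int(nrow(pos), n_trips, replace = TRUE, prob = pos$count))
  tibble::tibble(
    obs_id = seq_len(n_trips),
    zone_id = pos$zone_id[idx],
    resource_id = pos$resource_id[idx]
  )
}

#' Pair sampled trips with random non-chosen alternatives
#'
#' For each trip, samples `n_alt` distinct resources uniformly without
#' replacement from all resources of the type excluding the chosen one;
#' each observation gets an independent draw. If fewer than `n_alt` other
#' resources exist, all of them are used. Uniform sampling of alternatives
#' keeps multinomial-logit estimation consistent without correction terms.
#'
#' @param trips Output of [sample_trips()].
#' @param resources Resource tibble (the full inventory of the type).
#' @param n_alt Number of non-chosen alternatives (default 10).
#' @param seed Integer seed.
#' @return Long tibble `obs_id`, `zone_id`, `resource_id`, `chosen`, with
#'   `1 + min(n_alt, n_resources - 1)` rows per observation.
#' @export
sample_alternatives <- function(trips, resources, n_alt = 10, seed) {
  if (missing(seed)) stop_validation("seed is required for sample_alternatives")
  ids <- resources$resource_id
  if (length(ids) < 2) {
    stop_validation("need at least two resources to form a choice contrast")
  }
  if (!all(trips$resource_id %in% ids)) {
    stop_validation("chosen resource not present in resource table")
  }
  k <- min(n_alt, length(ids) - 1)
  alt_mat <- withr::with_seed(as.integer(seed), {
    vapply(trips$resource_id, function(ch) {
      pool <- ids[ids != ch]
      if (length(pool) == k) pool else sample(pool, k)
    }, character(k))
  })
  alts <- tibble::tibble(
    obs_id = rep(trips$obs_id, each = k),
    zone_id = rep(trips$zone_id, each = k),
    resource_id = as.vector(alt_mat),
    chosen = FALSE
  )
  chosen <- tibble::tibble(
    obs_id = trips$obs_id, zone_id = trips$zone_id,
    resource_id = trips$resource_id, chosen = TRUE
  )
  dplyr::arrange(dplyr::bind_rows(alts, chosen), .data$obs_id,
                 dplyr::desc(.data$chosen), .data$resource_id)
}

#' Attach covariates to a sampled choice set
#'
#' Joins the impedance implied by the model specification and the declared
#' destination-attribute transforms onto the long alternative table. Any
#' observation containing an unreachable pair or a non-finite covariate is
#' dropped whole (keeping the per-observation choice-set size constant);
#' the number of dropped observations is reported and recorded.
#'
#' @param alts Long alternative tibble from [sample_alternatives()].
#' @param skims Validated skim tibble.
#' @param resources Resource tibble of the spec's type.
#' @param spec A [model_spec()].
#' @param coeffs [mode_coefficients()] used when the impedance is the
#'   mode-choice logsum.
#' @param quiet Suppress the drop message.
#' @return A `choice_data` tibble: `obs_id`, `zone_id`, `resource_id`,
#'   `chosen`, one column per covariate; attributes `spec`, `covariates`,
#'   `n_dropped`.
#' @export
attach_covariates <- function(alts, skims, resources, spec,
                              coeffs = mode_coefficients(), quiet = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  imp <- impedance_matrix(skims, coeffs, kind = spec$impedance)
  out <- dplyr::left_join(alts, imp, by = c("zone_id", "resource_id"))
  out$reachable[is.na(out$reachable)] <- FALSE
  names(out)[names(out) == "impedance"] <- spec$impedance

  keep_cols <- c("resource_id", spec$terms$attribute)
  attrs <- resources[keep_cols]
  for (i in seq_len(nrow(spec$terms))) {
    a <- spec$terms$attribute[i]
    v <- as.numeric(attrs[[a]])
    attrs[[a]] <- if (spec$terms$transform[i] == "log") log(v) else v
  }
  names(attrs) <- c("resource_id", covariate_names(spec)[-1])
  out <- dplyr::left_join(out, attrs, by = "resource_id")

  covars <- covariate_names(spec)
  cov_ok <- rowSums(!is.finite(as.matrix(out[covars]))) == 0
  bad_obs <- unique(out$obs_id[!out$reachable | !cov_ok])
  n_dropped <- length(bad_obs)
  if (n_dropped > 0 && !quiet) {
    message(sprintf(
      "attach_covariates: dropped %d of %d observations with unreachable or non-finite alternatives",
      n_dropped, dplyr::n_distinct(out$obs_id)))
  }
  out <- out[!(out$obs_id %in% bad_obs), ]
  out$reachable <- NULL
  structure(out, spec = spec, covariates = covars, n_dropped = n_dropped,
            class = c("choice_data", class(out)))
}

#' Serialize a choice dataset to CSV for audit or re-estimation
#'
#' @param data A `choice_data` tibble.
#' @param path File path.
#' @export
write_choice_data <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

#' @rdname write_choice_data
#' @param spec The [model_spec()] the dataset was built with (restores the
#'   covariate metadata).
#' @export
read_choice_data <- function(path, spec) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  covars <- covariate_names(spec)
  require_columns(df, c("obs_id", "zone_id", "resource_id", "chosen", covars),
                  "choice dataset")
  df$chosen <- coerce_flag(df$chosen, "chosen")
  structure(df, spec = spec, covariates = covars, n_dropped = NA_integer_,
            class = c("choice_data", class(df)))
}
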