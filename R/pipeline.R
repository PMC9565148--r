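# Pipeline stages binding the modules together through files on disk:
# simulate -> build-dataset -> estimate -> access -> equity. Each stage is
# a plain function over a declarative run configuration; a thin command
# line wrapper lives at inst/exec/uaccess. Stages exchange data only via
# files, are idempotent given identical config and seed, and log their
# seeds, drop counts, and convergence diagnostics to a run log.

default_run_config <- function() {
  list(
    out_dir = "uaccess_run",
    seed = 42,
    region = list(),
    mode_choice = list(),
    models = list(
      park = list(impedance = "mcls"),
      grocery = list(impedance = "mcls"),
      library = list(impedance = "mcls")
    ),
    buffers = list(
      park = list(mode = "walk", t_star = 5),
      grocery = list(mode = "auto", t_star = 5),
      library = list(mode = "auto", t_star = 10)
    ),
    sampling = list(n_trips = 10000, n_alt = 10)
  )
}

#' Load a pipeline run configuration
#'
#' Reads a YAML configuration and merges it over the defaults: buffer
#' thresholds of a 5-minute walk for parks, a 5-minute drive for grocery
#' stores and a 10-minute drive for libraries; full-specification models
#' with the mode-choice logsum impedance; 10,000 estimation trips with 10
#' sampled alternatives. Blocks: `out_dir`, `seed`, `region` (overrides for
#' [region_config()]), `mode_choice` (overrides for
#' [mode_coefficients()]), `models`, `buffers`, `sampling`.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list merged last (e.g., command-line flags).
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_validation(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, user)
  }
  cfg <- modifyList(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

run_log <- function(cfg, stage, lines) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  entry <- sprintf("[%s] %s | config %s | %s", stamp, stage,
                   rlang::hash(unclass(cfg)), lines)
  cat(entry, sep = "\n")
  cat(entry, file = file.path(cfg$out_dir, "run_log.txt"),
      sep = "\n", append = TRUE)
}

cfg_mode_coeffs <- function(cfg) do.call(mode_coefficients, cfg$mode_choice)

cfg_region_config <- function(cfg) {
  do.call(region_config, modifyList(cfg$region, list(seed = cfg$seed)))
}

stage_input <- function(cfg, fname, producer) {
  path <- file.path(cfg$out_dir, fname)
  if (!file.exists(path)) {
    stop_validation(sprintf("missing %s; run `%s` first", path, producer))
  }
  path
}

#' Pipeline stage: simulate a synthetic region
#'
#' Writes zones, per-type resources, skims, flows, and the ground-truth
#' coefficient file under `cfg$out_dir`.
#'
#' @param cfg A `run_config` ([read_run_config()]).
#' @return The simulation bundle, invisibly.
#' @export
run_simulate <- function(cfg) {
  sim <- simulate_region(cfg_region_config(cfg), out_dir = cfg$out_dir,
                         coeffs = cfg_mode_coeffs(cfg))
  run_log(cfg, "simulate",
          sprintf("seed=%d zones=%d resources=%s", cfg$seed,
                  nrow(sim$zones),
                  paste(vapply(sim$resources, nrow, integer(1)), collapse = "/")))
  invisible(sim)
}

#' Pipeline stage: build the choice estimation dataset
#'
#' Samples estimation trips from the flow table, pairs them with random
#' alternatives, attaches covariates per the configured model spec, and
#' writes `choice_data_<rtype>.csv`.
#'
#' @param cfg A `run_config`.
#' @param rtype Resource type.
#' @return The `choice_data` tibble, invisibly.
#' @export
run_build <- function(cfg, rtype) {
  rtype <- match.arg(rtype, resource_types())
  zones <- read_zones(stage_input(cfg, "zones.csv", "simulate"))
  resources <- read_resources(
    stage_input(cfg, sprintf("resources_%s.csv", rtype), "simulate"), rtype)
  skims <- read_skims(stage_input(cfg, sprintf("skims_%s.csv", rtype), "simulate"),
                      zones, resources)
  flows <- read_flows(stage_input(cfg, sprintf("flows_%s.csv", rtype), "simulate"),
                      zones, resources)
  spec <- do.call(model_spec, c(list(rtype = rtype), cfg$models[[rtype]]))
  seed_trips <- cfg$seed + 100L
  seed_alts <- cfg$seed + 200L
  trips <- sample_trips(flows, n_trips = cfg$sampling$n_trips, seed = seed_trips)
  alts <- sample_alternatives(trips, resources, n_alt = cfg$sampling$n_alt,
                              seed = seed_alts)
  data <- attach_covariates(alts, skims, resources, spec,
                            coeffs = cfg_mode_coeffs(cfg), quiet = TRUE)
  write_choice_data(data, file.path(cfg$out_dir,
                                    sprintf("choice_data_%s.csv", rtype)))
  run_log(cfg, paste0("build-dataset:", rtype),
          sprintf("seed_trips=%d seed_alts=%d n_obs=%d dropped=%d",
                  seed_trips, seed_alts, dplyr::n_distinct(data$obs_id),
                  attr(data, "n_dropped")))
  invisible(data)
}

#' Pipeline stage: estimate the destination choice model
#'
#' Fits the configured specification, writes a text report mirroring the
#' conventional coefficient-table layout plus a machine-readable
#' coefficient file.
#'
#' @inheritParams run_build
#' @return The fitted `choice_model`, invisibly.
#' @export
run_estimate <- function(cfg, rtype) {
  rtype <- match.arg(rtype, resource_types())
  spec <- do.call(model_spec, c(list(rtype = rtype), cfg$models[[rtype]]))
  data <- read_choice_data(
    stage_input(cfg, sprintf("choice_data_%s.csv", rtype), "build-dataset"),
    spec)
  fit <- mnl_fit(data)
  writeLines(model_report(setNames(list(fit), rtype)),
             file.path(cfg$out_dir, sprintf("model_%s.txt", rtype)))
  write_coefficients(fit, file.path(cfg$out_dir,
                                    sprintf("coefficients_%s.csv", rtype)))
  run_log(cfg, paste0("estimate:", rtype),
          sprintf("converged=%s iterations=%d loglik=%.1f rho_sq=%.3f",
                  fit$converged, fit$iterations, fit$loglik, fit$rho_sq))
  invisible(fit)
}

#' Pipeline stage: accessibility surfaces
#'
#' Computes the logsum surface from the estimated coefficients and the
#' configured buffer surface, and writes both as CSV.
#'
#' @inheritParams run_build
#' @return Named list of the two surfaces, invisibly.
#' @export
run_access <- function(cfg, rtype) {
  rtype <- match.arg(rtype, resource_types())
  zones <- read_zones(stage_input(cfg, "zones.csv", "simulate"))
  resources <- read_resources(
    stage_input(cfg, sprintf("resources_%s.csv", rtype), "simulate"), rtype)
  skims <- read_skims(stage_input(cfg, sprintf("skims_%s.csv", rtype), "simulate"))
  coefs <- read_coefficients(
    stage_input(cfg, sprintf("coefficients_%s.csv", rtype), "estimate"))
  spec <- do.call(model_spec, c(list(rtype = rtype), cfg$models[[rtype]]))
  ls <- logsum_access(coefs, zones, resources, skims,
                      coeffs = cfg_mode_coeffs(cfg), spec = spec)
  bcfg <- cfg$buffers[[rtype]]
  bf <- buffer_access(zones, resources, skims, mode = bcfg$mode,
                      t_star = bcfg$t_star)
  write_surface(ls, file.path(cfg$out_dir, sprintf("access_logsum_%s.csv", rtype)))
  write_surface(bf, file.path(cfg$out_dir, sprintf("access_buffer_%s.csv", rtype)))
  run_log(cfg, paste0("access:", rtype),
          sprintf("buffer=%s@%gmin logsum_mean=%.3f",
                  bcfg$mode, bcfg$t_star, mean(ls$value, na.rm = TRUE)))
  invisible(list(logsum = ls, buffer = bf))
}

#' Pipeline stage: equity summary
#'
#' Classifies zones by access status across all three resource types and
#' writes household counts (total and low-income) for the
#' outside-all-buffers group, the below-mean-logsum group, and their
#' overlap.
#'
#' @inheritParams run_build
#' @return The `equity_table`, invisibly.
#' @export
run_equity <- function(cfg) {
  zones <- read_zones(stage_input(cfg, "zones.csv", "simulate"))
  read_surface <- function(fname, measure, rt) {
    df <- readr::read_csv(stage_input(cfg, fname, "access"),
                          show_col_types = FALSE, progress = FALSE)
    new_access_surface(df[c("zone_id", "value")], measure, rt,
                       if (measure == "buffer") cfg$buffers[[rt]] else list())
  }
  buffers <- lapply(setNames(nm = resource_types()), function(rt)
    read_surface(sprintf("access_buffer_%s.csv", rt), "buffer", rt))
  logsums <- lapply(setNames(nm = resource_types()), function(rt)
    read_surface(sprintf("access_logsum_%s.csv", rt), "logsum", rt))
  flags <- classify_zones(buffers, logsums, zones)
  eq <- equity_summary(flags, zones)
  write_equity(eq, file.path(cfg$out_dir, "equity.csv"))
  writeLines(format_equity(eq), file.path(cfg$out_dir, "equity.txt"))
  run_log(cfg, "equity",
          sprintf("hh_outside_buffers=%d hh_below_mean=%d hh_both=%d",
                  eq$hh_outside_buffers, eq$hh_below_mean_logsum, eq$hh_both))
  invisible(eq)
}

#' Run the full pipeline on a configuration
#'
#' simulate, then build-dataset / estimate / access for every resource
#' type, then equity.
#'
#' @param cfg A `run_config`.
#' @return The `equity_table`, invisibly.
#' @export
run_pipeline <- function(cfg) {
  run_simulate(cfg)
  for (rt in resource_types()) {
    run_build(cfg, rt)
    run_estimate(cfg, rt)
    run_access(cfg, rt)
  }
  run_equity(cfg)
}
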