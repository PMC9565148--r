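#' Reference model estimates from the Utah County application
#'
#' Bundled coefficient estimates and fit statistics from a published
#' application of this methodology to parks, grocery stores, and libraries
#' in Utah County, Utah (destination choice models estimated on 10,000
#' trips sampled from commercial location-based-services data, each with
#' ten randomly sampled non-chosen alternatives). These serve as worked
#' examples for the fit-statistic conventions, as realistic ground-truth
#' coefficients for the synthetic generator, and as the inputs of the
#' willingness-to-travel calculation (e.g., the ratio of the convenience
#' store and drive-time coefficients of the full grocery model, about
#' 4.97 minutes).
#'
#' @param which `"fit_stats"` (per-model `n_obs`, log-likelihood,
#'   rho-squared, coefficient count) or `"coefficients"` (per-term
#'   estimates and t-statistics).
#' @return A tibble.
#' @export
#' @examples
#' fs <- published_estimates("fit_stats")
#' with(fs[fs$rtype == "park" & fs$model == "Car", ],
#'      mcfadden_rho(loglik, n_obs, 11))  # 0.591
published_estimates <- function(which = c("fit_stats", "coefficients")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("published_", which, ".csv"),
                      package = "utilaccess", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
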