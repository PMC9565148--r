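# Multinomial logit destination-choice estimation by maximum likelihood.
#
# The model: P_ij = exp(V_ij) / sum_j' exp(V_ij'), with V_ij linear in an
# impedance term and destination attributes. Estimation is Newton-Raphson
# on the analytic score and Hessian, with step-halving and a quasi-Newton
# fallback; inference comes from the observed information at the optimum.

extract_design <- function(data, covariates = NULL) {
  if (is.null(covariates)) covariates <- attr(data, "covariates")
  if (is.null(covariates)) {
    stop_validation("covariates must be supplied (or present as an attribute)")
  }
  require_columns(data, c("obs_id", "chosen", covariates), "choice dataset")
  X <- as.matrix(tibble::as_tibble(data)[covariates])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) {
    stop_validation("non-finite covariate values; drop such observations upstream")
  }
  obs <- factor(data$obs_id, levels = unique(data$obs_id))
  y <- as.logical(data$chosen)
  n_chosen <- tapply(y, obs, sum)
  if (any(n_chosen != 1)) {
    stop_validation("every observation must have exactly one chosen alternative")
  }
  list(X = X, y = y, obs = obs, covariates = covariates)
}

# Softmax within observation groups, max-shift stabilized.
softmax_by_obs <- function(eta, obs) {
  m <- stats::ave(eta, obs, FUN = max)
  e <- exp(eta - m)
  denom <- stats::ave(e, obs, FUN = sum)
  e / denom
}

#' Choice probabilities under a multinomial logit
#'
#' Computes `P_ij = exp(V_ij) / sum_j' exp(V_ij')` within each observation's
#' alternative set, with max-shift stabilization. Probabilities are positive
#' and sum to one within each observation to machine precision.
#'
#' @param data A `choice_data` tibble (or any tibble with `obs_id`,
#'   `chosen`, and the covariate columns).
#' @param coef Named coefficient vector aligned with the covariates.
#' @param covariates Covariate column names; defaults to the dataset's
#'   `covariates` attribute.
#' @return Numeric vector of probabilities, one per row of `data`.
#' @export
choice_probabilities <- function(data, coef, covariates = NULL) {
  d <- extract_design(data, covariates)
  eta <- drop(d$X %*% coef[d$covariates])
  softmax_by_obs(eta, d$obs)
}

mnl_ll_parts <- function(beta, d) {
  eta <- drop(d$X %*% beta)
  p <- softmax_by_obs(eta, d$obs)
  list(p = p, ll = sum(log(p[d$y])))
}

#' Log-likelihood and score of a multinomial logit
#'
#' `mnl_loglik()` returns `sum over observations of log P(chosen)`;
#' `mnl_score()` returns its analytic gradient
#' `X'(y - p)`, which matches central finite differences of the
#' log-likelihood.
#'
#' @inheritParams choice_probabilities
#' @return A scalar (`mnl_loglik`) or named vector (`mnl_score`).
#' @export
mnl_loglik <- function(coef, data, covariates = NULL) {
  d <- extract_design(data, covariates)
  mnl_ll_parts(coef[d$covariates], d)$ll
}

#' @rdname mnl_loglik
#' @export
mnl_score <- function(coef, data, covariates = NULL) {
  d <- extract_design(data, covariates)
  p <- mnl_ll_parts(coef[d$covariates], d)$p
  drop(crossprod(d$X, d$y - p))
}

# Analytic Hessian of the log-likelihood:
#   H = -(X' diag(p) X - sum_obs g_o g_o'),  g_o = X_o' p_o
mnl_hessian <- function(beta, d) {
  p <- mnl_ll_parts(beta, d)$p
  G <- rowsum(d$X * p, d$obs, reorder = FALSE)
  -(crossprod(d$X, d$X * p) - crossprod(G))
}

check_identification <- function(d) {
  centered <- d$X - rowsum(d$X, d$obs, reorder = FALSE)[d$obs, , drop = FALSE] /
    as.vector(table(d$obs))[as.integer(d$obs)]
  rng <- apply(abs(centered), 2, max)
  flat <- d$covariates[rng < 1e-12]
  if (length(flat) > 0) {
    stop_validation(sprintf(
      "covariate(s) constant across alternatives within every observation (not identified): %s",
      paste(flat, collapse = ", ")))
  }
}

#' Fit a multinomial logit destination choice model
#'
#' Maximum likelihood via Newton-Raphson with step-halving; if the Hessian
#' is not negative definite at an iterate, a BFGS pass on the analytic
#' score is used before resuming Newton steps. Convergence is declared on
#' the gradient norm (`max |score| < tol`), not on parameter change.
#' Standard errors come from the inverse observed information at the
#' optimum. The null log-likelihood is the equal-shares value
#' `sum_obs log(1 / J_obs)` over each observation's alternative-set size,
#' and McFadden's rho-squared is `1 - loglik / loglik_null`.
#'
#' @param data A `choice_data` tibble ([attach_covariates()]).
#' @param covariates Covariate columns; defaults to the dataset attribute.
#' @param start Optional start values (default zero).
#' @param tol Gradient convergence tolerance (default 1e-6).
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `choice_model` with elements `coef`, `vcov`,
#'   `t_stats`, `loglik`, `loglik_null`, `rho_sq`, `n_obs`,
#'   `n_alt_per_obs`, `converged`, `iterations`, `spec`.
#' @export
mnl_fit <- function(data, covariates = NULL, start = NULL, tol = 1e-6,
                    max_iter = 100) {
  d <- extract_design(data, covariates)
  K <- ncol(d$X)
  if (nrow(d$X) == 0) stop_validation("empty dataset")
  check_identification(d)

  beta <- if (is.null(start)) rep(0, K) else as.numeric(start[d$covariates])
  ll <- mnl_ll_parts(beta, d)$ll
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    g <- drop(crossprod(d$X, d$y - mnl_ll_parts(beta, d)$p))
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    H <- mnl_hessian(beta, d)
    step <- tryCatch(solve(-H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      # non-PD information: quasi-Newton rescue on the analytic score
      opt <- stats::optim(beta, fn = function(b) -mnl_ll_parts(b, d)$ll,
                          gr = function(b) -drop(crossprod(d$X, d$y - mnl_ll_parts(b, d)$p)),
                          method = "BFGS", control = list(maxit = 200))
      beta <- opt$par
      ll <- -opt$value
      next
    }
    # step-halving on likelihood decrease
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_cand <- mnl_ll_parts(cand, d)$ll
      if (is.finite(ll_cand) && ll_cand >= ll - 1e-10) break
      lambda <- lambda / 2
      if (lambda < 1e-8) { cand <- beta; ll_cand <- ll; break }
    }
    beta <- cand
    ll <- ll_cand
    if (max(abs(beta)) > 50) {
      stop_validation(paste(
        "estimates diverging (|coef| > 50): possible perfect separation;",
        "a covariate may perfectly predict the chosen alternative"))
    }
  }
  if (!converged) {
    g <- drop(crossprod(d$X, d$y - mnl_ll_parts(beta, d)$p))
    converged <- max(abs(g)) < tol
    if (!converged) warn(sprintf("mnl_fit did not converge in %d iterations (max |score| = %.2e)",
                                 max_iter, max(abs(g))))
  }

  H <- mnl_hessian(beta, d)
  vcov <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, K, K))
  dimnames(vcov) <- list(d$covariates, d$covariates)
  coef <- setNames(as.numeric(beta), d$covariates)
  J_obs <- as.vector(table(d$obs))
  n_obs <- length(J_obs)
  ll0 <- sum(log(1 / J_obs))
  se <- sqrt(diag(vcov))

  structure(list(
    coef = coef, vcov = vcov, se = se, t_stats = coef / se,
    loglik = ll, loglik_null = ll0,
    n_obs = n_obs,
    n_alt_per_obs = if (length(unique(J_obs)) == 1) J_obs[1] else NA_integer_,
    rho_sq = 1 - ll / ll0,
    converged = converged, iterations = iter,
    spec = attr(data, "spec")
  ), class = "choice_model")
}

#' @export
coef.choice_model <- function(object, ...) object$coef

#' @export
vcov.choice_model <- function(object, ...) object$vcov

#' @export
logLik.choice_model <- function(object, ...) {
  structure(object$loglik, df = length(object$coef), nobs = object$n_obs,
            class = "logLik")
}

#' @export
print.choice_model <- function(x, ...) {
  cat("Multinomial logit destination choice model\n")
  if (!is.null(x$spec)) {
    cat(sprintf("  resource type: %s; impedance: %s\n",
                x$spec$rtype, x$spec$impedance))
  }
  tab <- sprintf("  %-22s %10.3f  (%.3f)", names(x$coef), x$coef, x$t_stats)
  cat(tab, sep = "\n")
  cat(sprintf("  Num.Obs.          %d\n", x$n_obs))
  cat(sprintf("  Log Likelihood    %.1f\n", x$loglik))
  cat(sprintf("  McFadden Rho-Sq   %.3f\n", x$rho_sq))
  cat("  (t-statistics in parentheses)\n")
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' McFadden's rho-squared against the equal-shares null
#'
#' `1 - loglik / (n_obs * log(1/n_alt))`: the fit statistic of a discrete
#' choice model against a null that assigns each of `n_alt` alternatives an
#' equal share.
#'
#' @param loglik Fitted log-likelihood.
#' @param n_obs Number of observations.
#' @param n_alt Alternatives per observation (e.g., 11 when one chosen plus
#'   ten sampled alternatives).
#' @return Scalar rho-squared.
#' @export
#' @examples
#' mcfadden_rho(-8945.6, 9119, 11)  # 0.591
mcfadden_rho <- function(loglik, n_obs, n_alt) {
  stopifnot(n_obs >= 1, n_alt >= 1)
  1 - loglik / (n_obs * log(1 / n_alt))
}

adjusted_rho <- function(loglik, k, loglik_null) 1 - (loglik - k) / loglik_null

#' Non-nested likelihood comparison of two choice models
#'
#' Upper-bound p-value for the hypothesis that the model with the lower
#' adjusted rho-squared is the true specification, against a non-nested
#' alternative fitted to the same dataset (Horowitz bound, in the
#' adjusted-rho-squared form): with `z` the adjusted rho-squared difference,
#' `p <= Phi(-sqrt(-2 z LL0 + (K_high - K_low)))`. A small value rejects
#' equivalence in favor of the higher-rho model; the statistic is an upper
#' bound, so failure to reject is conservative.
#'
#' Adjusted rho-squared is `1 - (LL - K)/LL0` with `K` the number of
#' estimated coefficients.
#'
#' @param model_low,model_high `choice_model` objects fitted to the same
#'   dataset (identical null log-likelihood), ordered so `model_high` has
#'   the weakly higher adjusted rho-squared.
#' @return An object of class `htest` with the bound as `p.value`.
#' @export
horowitz_test <- function(model_low, model_high) {
  ll0 <- model_low$loglik_null
  if (abs(ll0 - model_high$loglik_null) > 1e-6 * abs(ll0)) {
    stop_validation("models must share the same dataset (null log-likelihoods differ)")
  }
  k_l <- length(model_low$coef)
  k_h <- length(model_high$coef)
  z <- adjusted_rho(model_high$loglik, k_h, ll0) -
    adjusted_rho(model_low$loglik, k_l, ll0)
  if (z < 0) {
    stop_validation("model_high must have the higher adjusted rho-squared; swap the arguments")
  }
  arg <- -2 * z * ll0 + (k_h - k_l)
  p <- pnorm(-sqrt(max(arg, 0)))
  structure(list(
    statistic = c(z = z), p.value = p,
    method = "Horowitz non-nested likelihood bound (adjusted rho-squared form)",
    alternative = "the higher-rho-squared model fits better",
    data.name = "two choice models on a common dataset",
    note = "p-value is a one-sided upper bound"
  ), class = "htest")
}

#' Text report of one or more fitted models
#'
#' Side-by-side coefficient table with t-statistics in parentheses plus
#' Num.Obs., log-likelihood, and McFadden rho-squared, in the conventional
#' layout of destination-choice model tables.
#'
#' @param ... Named `choice_model` objects (names become column headers).
#' @return Character vector of report lines (invisibly printed-friendly).
#' @export
model_report <- function(...) {
  models <- list(...)
  if (length(models) == 1 && is.list(models[[1]]) &&
      !inherits(models[[1]], "choice_model")) {
    models <- models[[1]]
  }
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- paste("Model", seq_along(models))
  }
  terms <- unique(unlist(lapply(models, function(m) names(m$coef))))
  wide <- 24
  fmt_cell <- function(m, term) {
    if (!term %in% names(m$coef)) return(sprintf("%*s", wide, ""))
    sprintf("%*s", wide, sprintf("%.3f (%.3f)", m$coef[term], m$t_stats[term]))
  }
  header <- paste0(sprintf("%-22s", ""), paste0(sprintf("%*s", wide, names(models)),
                                                collapse = ""))
  body <- vapply(terms, function(tm) {
    paste0(sprintf("%-22s", tm),
           paste0(vapply(models, fmt_cell, character(1), term = tm), collapse = ""))
  }, character(1))
  stats_rows <- c(
    paste0(sprintf("%-22s", "Num.Obs."),
           paste0(vapply(models, function(m) sprintf("%*d", wide, m$n_obs),
                         character(1)), collapse = "")),
    paste0(sprintf("%-22s", "Log Likelihood"),
           paste0(vapply(models, function(m) sprintf("%*.1f", wide, m$loglik),
                         character(1)), collapse = "")),
    paste0(sprintf("%-22s", "McFadden Rho-Sq"),
           paste0(vapply(models, function(m) sprintf("%*.3f", wide, m$rho_sq),
                         character(1)), collapse = ""))
  )
  c(header, body, stats_rows, "t-statistics in parentheses")
}

#' Save or load fitted coefficients for reuse in accessibility calculation
#'
#' @param model A `choice_model`.
#' @param path File path (CSV with columns `term`, `estimate`, `se`).
#' @export
write_coefficients <- function(model, path) {
  readr::write_csv(tibble::tibble(term = names(model$coef),
                                  estimate = as.numeric(model$coef),
                                  se = as.numeric(model$se)), path)
  invisible(path)
}

#' @rdname write_coefficients
#' @return `read_coefficients()` returns a named numeric vector.
#' @export
read_coefficients <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  setNames(df$estimate, df$term)
}
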