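# A small hand-rolled dataset builder: `u` is a list of per-observation
# covariate matrices (rows = alternatives), chosen alternative first.
make_cd <- function(u, covariates = paste0("x", seq_len(ncol(u[[1]])))) {
  rows <- purrr::imap(u, function(m, i) {
    colnames(m) <- covariates
    tibble::as_tibble(m) |>
      dplyr::mutate(obs_id = i, chosen = dplyr::row_number() == 1,
                    zone_id = "A", resource_id = paste0("r", dplyr::row_number()))
  })
  dplyr::bind_rows(rows)
}

test_that("choice probabilities normalize and respect symmetry", {
  cd <- make_cd(list(matrix(c(2, 2), 2, 1)))
  p <- choice_probabilities(cd, c(x1 = 1.3), covariates = "x1")
  expect_equal(p, c(0.5, 0.5))

  cd11 <- make_cd(list(matrix(rnorm(11), 11, 1)))
  p11 <- choice_probabilities(cd11, c(x1 = 0), covariates = "x1")
  expect_equal(p11, rep(1 / 11, 11))
  expect_lt(abs(sum(p11) - 1), 1e-12)

  # a 20-utility gap concentrates virtually all probability
  cdgap <- make_cd(list(matrix(c(20, 0, 0), 3, 1)))
  pgap <- choice_probabilities(cdgap, c(x1 = 1), covariates = "x1")
  expect_gt(pgap[1], 0.9999)

  # probabilities sum to one within each observation, even far from zero
  set.seed(1)
  cdr <- make_cd(purrr::map(1:5, ~ matrix(rnorm(8, sd = 30), 4, 2)))
  pr <- choice_probabilities(cdr, c(x1 = 2, x2 = -3),
                             covariates = c("x1", "x2"))
  sums <- tapply(pr, cdr$obs_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("log-likelihood hits closed forms at zero and for binary logit", {
  set.seed(2)
  cd <- make_cd(purrr::map(1:7, ~ matrix(rnorm(22), 11, 2)))
  expect_equal(mnl_loglik(c(x1 = 0, x2 = 0), cd,
                          covariates = c("x1", "x2")),
               7 * log(1 / 11))

  # one obs, two alternatives, utility gap D for the chosen
  D <- 0.8
  cd2 <- make_cd(list(matrix(c(D, 0), 2, 1)))
  expect_equal(mnl_loglik(c(x1 = 1), cd2, covariates = "x1"),
               -log(1 + exp(-D)))
})

test_that("the analytic score matches central finite differences", {
  set.seed(3)
  cd <- make_cd(purrr::map(1:12, ~ matrix(rnorm(15), 5, 3)))
  covs <- c("x1", "x2", "x3")
  beta <- c(x1 = 0.4, x2 = -0.9, x3 = 0.15)
  g <- mnl_score(beta, cd, covariates = covs)
  h <- 1e-5
  fd <- vapply(seq_along(beta), function(k) {
    bp <- beta; bp[k] <- bp[k] + h
    bm <- beta; bm[k] <- bm[k] - h
    (mnl_loglik(bp, cd, covariates = covs) -
       mnl_loglik(bm, cd, covariates = covs)) / (2 * h)
  }, numeric(1))
  expect_equal(unname(g), fd, tolerance = 1e-6)
})

test_that("the fitted optimum matches a one-dimensional grid/golden oracle", {
  set.seed(4)
  u <- purrr::map(1:3, ~ matrix(rnorm(3), 3, 1))
  cd <- make_cd(u)
  fit <- mnl_fit(cd, covariates = "x1")
  # independent oracle: direct softmax log-likelihood + golden-section search
  oracle_ll <- function(b) {
    sum(vapply(u, function(m) {
      v <- m[, 1] * b
      v[1] - max(v) - log(sum(exp(v - max(v))))
    }, numeric(1)))
  }
  opt <- optimize(oracle_ll, c(-10, 10), maximum = TRUE, tol = 1e-10)
  expect_equal(unname(coef(fit)), opt$maximum, tolerance = 1e-4)
  expect_equal(fit$loglik, opt$objective, tolerance = 1e-8)
})

test_that("optimum properties: vanishing score, improvement over null", {
  res <- small_fit(seed = 31, n_trips = 400)
  fit <- res$fit
  expect_true(fit$converged)
  g <- mnl_score(coef(fit), res$data)
  expect_lt(max(abs(g)), 1e-6)
  expect_gte(fit$loglik, fit$loglik_null)
  expect_equal(fit$rho_sq, 1 - fit$loglik / fit$loglik_null)
  expect_equal(unname(fit$t_stats), unname(coef(fit) / sqrt(diag(vcov(fit)))))
  # vcov is positive definite at the optimum
  expect_true(all(eigen(vcov(fit), symmetric = TRUE)$values > 0))
})

test_that("degenerate designs are diagnosed before or during optimization", {
  # covariate constant across alternatives within every observation
  cd <- make_cd(purrr::map(1:4, ~ cbind(rnorm(3), 1)))
  expect_error(mnl_fit(cd, covariates = c("x1", "x2")),
               "not identified")

  # a covariate that perfectly predicts the choice diverges
  cd_sep <- make_cd(purrr::map(1:30, ~ matrix(c(0.1, 0, 0), 3, 1)))
  expect_error(mnl_fit(cd_sep, covariates = "x1"), "separation")
})

test_that("estimates agree with an independent conditional-logit fit", {
  skip_if_not_installed("survival")
  library(survival)
  res <- small_fit(seed = 41, n_trips = 500)
  df <- tibble::as_tibble(res$data)
  covs <- attr(res$data, "covariates")
  fml <- stats::as.formula(paste(
    "chosen ~", paste(covs, collapse = " + "), "+ strata(obs_id)"))
  cl <- survival::clogit(fml, data = df)
  expect_equal(coef(res$fit), coef(cl)[covs], tolerance = 1e-5)
  expect_equal(sqrt(diag(vcov(res$fit))), sqrt(diag(vcov(cl)))[covs],
               tolerance = 1e-4)
  expect_equal(res$fit$loglik, as.numeric(stats::logLik(cl)), tolerance = 1e-7)
})

test_that("rho-squared recomputes published fit statistics from LL and N", {
  expect_equal(round(mcfadden_rho(-8945.6, 9119, 11), 3), 0.591)
  expect_equal(round(mcfadden_rho(-14256.7, 10000, 11), 3), 0.405)
  expect_equal(mcfadden_rho(120 * log(1 / 11), 120, 11), 0)
})

test_that("the non-nested likelihood bound behaves as a one-sided bound", {
  mk <- function(ll, k, ll0, n = 9119) {
    structure(list(coef = setNames(rep(0, k), paste0("b", 1:k)),
                   loglik = ll, loglik_null = ll0, n_obs = n),
              class = "choice_model")
  }
  ll0 <- 9119 * log(1 / 11)
  # identical fits: no evidence either way
  expect_equal(horowitz_test(mk(-4603.5, 6, ll0), mk(-4603.5, 6, ll0))$p.value,
               0.5)
  # the worked example from rounded published log-likelihoods
  p <- horowitz_test(mk(-4603.5, 6, ll0), mk(-4603.2, 6, ll0))$p.value
  expect_equal(p, 0.2192890, tolerance = 1e-6)
  # a larger sample (|LL0|) at the same rho gap is stronger evidence
  p2 <- horowitz_test(mk(2 * -4603.5, 6, 2 * ll0), mk(2 * -4603.2, 6, 2 * ll0))$p.value
  expect_lt(p2, p)
  # misordered models are the caller's error
  expect_error(horowitz_test(mk(-4603.2, 6, ll0), mk(-4603.5, 6, ll0)),
               class = "utilaccess_validation_error")
})

test_that("model reports carry the conventional table furniture", {
  res <- small_fit(seed = 51, n_trips = 200)
  rep_lines <- model_report(park = res$fit)
  expect_true(any(grepl("Num.Obs.", rep_lines)))
  expect_true(any(grepl("McFadden Rho-Sq", rep_lines)))
  expect_true(any(grepl("t-statistics in parentheses", rep_lines)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_coefficients(res$fit, path)
  expect_equal(read_coefficients(path), coef(res$fit))
})
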