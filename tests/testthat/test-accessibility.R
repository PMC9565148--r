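# Coefficients for a one-covariate park utility: V = beta*t + gamma*log(acres)
park_spec1 <- function() {
  model_spec("park", impedance = "t_auto",
             terms = tibble::tibble(attribute = "acres", transform = "log"))
}

test_that("logsum access reduces to the utility for a single resource", {
  z <- tiny_zones(1)
  p <- tiny_parks(1, acres = exp(2))
  sk <- auto_skims(z, p, matrix(10, 1, 1))
  coef <- c(t_auto = -0.1, log_acres = 0.5)
  a <- logsum_access(coef, z, p, sk, spec = park_spec1())
  expect_equal(a$value, -0.1 * 10 + 0.5 * 2)
})

test_that("duplicating a resource with identical utility adds exactly ln 2", {
  z <- tiny_zones(2)
  p1 <- tiny_parks(1, acres = 5)
  p2 <- tiny_parks(2, acres = c(5, 5))
  p2$x <- c(1, 1); p2$y <- c(1, 1)
  t1 <- matrix(c(7, 12), 2, 1)
  a1 <- logsum_access(c(t_auto = -0.2, log_acres = 1), z, p1,
                      auto_skims(z, p1, t1), spec = park_spec1())
  a2 <- logsum_access(c(t_auto = -0.2, log_acres = 1), z, p2,
                      auto_skims(z, p2, cbind(t1, t1)), spec = park_spec1())
  expect_equal(a2$value, a1$value + log(2))
})

test_that("improving attributes or travel times never lowers logsum access", {
  set.seed(6)
  z <- tiny_zones(4)
  p <- tiny_parks(5, acres = rlnorm(5, 2))
  t <- matrix(runif(20, 2, 30), 4, 5)
  coef <- c(t_auto = -0.25, log_acres = 1.1)
  a0 <- logsum_access(coef, z, p, auto_skims(z, p, t), spec = park_spec1())
  p_up <- p; p_up$acres <- p$acres * 1.5
  a_attr <- logsum_access(coef, z, p_up, auto_skims(z, p, t), spec = park_spec1())
  expect_true(all(a_attr$value > a0$value))
  a_time <- logsum_access(coef, z, p, auto_skims(z, p, t * 0.8),
                          spec = park_spec1())
  expect_true(all(a_time$value > a0$value))
})

test_that("logsum access shifts uniformly under a constant utility shift", {
  set.seed(7)
  z <- tiny_zones(3)
  p <- tiny_parks(4, acres = rlnorm(4, 2))
  sk <- auto_skims(z, p, matrix(runif(12, 2, 25), 3, 4))
  coef <- c(t_auto = -0.2, log_acres = 1)
  a <- logsum_access(coef, z, p, sk, spec = park_spec1())
  p_scaled <- p; p_scaled$acres <- p$acres * 3  # shifts every utility by log 3
  a_s <- logsum_access(coef, z, p_scaled, sk, spec = park_spec1())
  expect_equal(a_s$value - a$value, rep(log(3), 3))
  # standardized surfaces are invariant to the shift entirely
  a_std <- logsum_access(coef, z, p, sk, spec = park_spec1(),
                         standardize = TRUE)
  a_s_std <- logsum_access(coef, z, p_scaled, sk, spec = park_spec1(),
                           standardize = TRUE)
  expect_equal(a_std$value, a_s_std$value)
})

test_that("buffer access uses the closed threshold of the isochrone measure", {
  z <- tiny_zones(1)
  p <- tiny_parks(1)
  at_50 <- buffer_access(z, p, auto_skims(z, p, matrix(5.0, 1, 1)),
                         mode = "auto", t_star = 5)
  at_51 <- buffer_access(z, p, auto_skims(z, p, matrix(5.1, 1, 1)),
                         mode = "auto", t_star = 5)
  expect_equal(at_50$value, 1)  # t = t* is inside
  expect_equal(at_51$value, 0)

  # cumulative counting: parks at 2, 4, 9 minutes with t* = 5
  p3 <- tiny_parks(3)
  cum <- buffer_access(z, p3, auto_skims(z, p3, matrix(c(2, 4, 9), 1)),
                       mode = "auto", t_star = 5, cumulative = TRUE)
  expect_equal(cum$value, 2)
  expect_error(buffer_access(z, p3, auto_skims(z, p3, matrix(c(2, 4, 9), 1)),
                             mode = "auto", t_star = 0),
               class = "utilaccess_validation_error")
})

test_that("gravity access is linear in size and collapses to nearest at high decay", {
  z <- tiny_zones(1)
  p <- tiny_parks(1)
  g <- gravity_access(z, p, auto_skims(z, p, matrix(0, 1, 1)), beta = 0.1)
  expect_equal(g$value, 1)  # S = 1, t = 0, exp(0)

  p2 <- tiny_parks(2, acres = c(3, 7))
  sk2 <- auto_skims(z, p2, matrix(c(4, 9), 1))
  g1 <- gravity_access(z, p2, sk2, size_attr = "acres", beta = 0.2)
  p2_double <- p2; p2_double$acres <- p2$acres * 2
  g2 <- gravity_access(z, p2_double, sk2, size_attr = "acres", beta = 0.2)
  expect_equal(g2$value, 2 * g1$value)

  # beta -> infinity: only the (floored-time) nearest resource survives
  ghi <- gravity_access(z, p2, sk2, beta = 50)
  expect_equal(ghi$value, exp(-50 * 4), tolerance = 1e-10)
  gpow <- gravity_access(z, p2, auto_skims(z, p2, matrix(c(0.5, 9), 1)),
                         decay = "power", beta = 50)
  expect_equal(gpow$value, 1)  # nearest floored to 1 minute, 1^-50 = 1
  expect_error(gravity_access(z, p2, sk2, beta = 0),
               class = "utilaccess_validation_error")
})

test_that("logsum access with pure exponential impedance is log-gravity", {
  set.seed(8)
  z <- tiny_zones(3)
  p <- tiny_parks(4)
  t <- matrix(runif(12, 1, 30), 3, 4)
  sk <- auto_skims(z, p, t)
  b <- 0.13
  spec0 <- model_spec("park", impedance = "t_auto",
                      terms = tibble::tibble(attribute = character(),
                                             transform = character()))
  a <- logsum_access(c(t_auto = -b), z, p, sk, spec = spec0)
  g <- gravity_access(z, p, sk, beta = b)
  expect_equal(a$value, log(g$value), tolerance = 1e-12)
})

test_that("surface comparison exposes quality variation at equal travel time", {
  # zones on a line with identical parks: logsum strictly decreases in
  # nearest travel time
  z <- tiny_zones(4)
  p <- tiny_parks(3)
  t <- outer(1:4, c(0, 10, 20), function(i, o) 3 * i + o)
  sk <- auto_skims(z, p, t)
  coef <- c(t_auto = -0.3, log_acres = 1)
  ls <- logsum_access(coef, z, p, sk, spec = park_spec1())
  bf <- buffer_access(z, p, sk, mode = "auto", t_star = 5)
  cmp <- compare_surfaces(bf, ls, z, p, sk)
  expect_equal(cmp$nearest_time, 3 * (1:4))
  expect_true(all(diff(cmp$logsum[order(cmp$nearest_time)]) < 0))

  # equal nearest time, different quality: same buffer flag, different logsum
  z2 <- tiny_zones(2)
  p2 <- tiny_parks(2, acres = c(2, 40))
  t2 <- matrix(c(4, 50, 50, 4), 2, 2)  # each zone is 4 min from one park
  sk2 <- auto_skims(z2, p2, t2)
  ls2 <- logsum_access(coef, z2, p2, sk2, spec = park_spec1())
  bf2 <- buffer_access(z2, p2, sk2, mode = "auto", t_star = 5)
  cmp2 <- compare_surfaces(bf2, ls2, z2, p2, sk2)
  expect_equal(cmp2$buffer, c(1, 1))
  expect_gt(abs(diff(cmp2$logsum)), 1)

  expect_error(compare_surfaces(bf2, ls2, z2, p2[0, ], sk2),
               class = "utilaccess_validation_error")
  expect_error(compare_surfaces(bf, ls2, z, p, sk),
               class = "utilaccess_validation_error")
})

test_that("zones with no reachable resource are flagged, not averaged in", {
  z <- tiny_zones(2)
  p <- tiny_parks(1)
  sk <- as_skims(tibble::tibble(
    zone_id = c("A", "B"), resource_id = "p1",
    t_auto = c(10, NA), t_transit_iv = NA, wt = NA, at = NA,
    t_walk = NA, d_walk = NA))
  a <- logsum_access(c(t_auto = -0.1, log_acres = 1), z, p, sk,
                     spec = park_spec1(), standardize = TRUE)
  expect_false(a$reachable[2])
  expect_true(is.na(a$value[2]))
  expect_equal(a$value[1], 0)  # mean over the one reachable zone
})
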