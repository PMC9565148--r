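test_that("zone CSV reading validates schema and invariants", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    zone_id = c("A", "B", "C"), x = 1:3, y = 0,
    households = c(10, 20, 30), frac_low_income = 0.2
  ), path)
  z <- read_zones(path)
  expect_equal(nrow(z), 3)
  expect_equal(z$zone_id, c("A", "B", "C"))

  readr::write_csv(tibble::tibble(
    zone_id = "A", x = 1, y = 0, households = -5, frac_low_income = 0.2
  ), path)
  expect_error(read_zones(path), class = "utilaccess_schema_error")

  readr::write_csv(tibble::tibble(
    zone_id = c("A", "A"), x = 1, y = 0, households = 5, frac_low_income = 0.2
  ), path)
  expect_error(read_zones(path), class = "utilaccess_validation_error")

  readr::write_csv(tibble::tibble(zone_id = "A", x = 1, y = 0), path)
  expect_error(read_zones(path), "households")
})

test_that("GeoJSON zones get shoelace centroids when coordinates are absent", {
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(zone_id = "sq", households = 10,
                             frac_low_income = 0.1),
           geometry = list(type = "Polygon", coordinates = list(list(
             list(0, 0), list(1, 0), list(1, 1), list(0, 1), list(0, 0))))),
      list(type = "Feature",
           properties = list(zone_id = "pt", households = 5,
                             frac_low_income = 0.2),
           geometry = list(type = "Point", coordinates = list(2, 3)))
    )
  )
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  z <- read_zones(path)
  expect_equal(z$x, c(0.5, 2))
  expect_equal(z$y, c(0.5, 3))
})

test_that("resource reading coerces flags and guards log-transformed sizes", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    resource_id = "g1", x = 0, y = 0, n_registers = 2, n_selfcheckout = 0,
    convenience = 1, other_nonstandard = 0, pharmacy = "true",
    ethnic_market = "false", other_merchandise = 0
  ), path)
  g <- read_resources(path, "grocery")
  expect_true(g$convenience)
  expect_true(g$pharmacy)
  expect_false(g$ethnic_market)
  expect_equal(g$n_registers, 2)

  readr::write_csv(tibble::tibble(
    resource_id = "l1", x = 0, y = 0, sqft = 0,
    offers_classes = 1, genealogy = 0
  ), path)
  expect_error(read_resources(path, "library"),
               class = "utilaccess_validation_error")
  expect_error(
    as_resources(tibble::tibble(resource_id = "p", x = 0, y = 0, acres = -1,
                                playground = 1, volleyball = 0,
                                basketball = 0, tennis = 0), "park"),
    class = "utilaccess_validation_error")
})

test_that("a full-scale park inventory reads back row for row", {
  n <- 582
  df <- tibble::tibble(
    resource_id = sprintf("p%03d", seq_len(n)),
    x = runif(n), y = runif(n), acres = rlnorm(n),
    playground = rbinom(n, 1, 0.5), volleyball = 0, basketball = 1, tennis = 0
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  expect_equal(nrow(read_resources(path, "park")), 582)
})

test_that("skim IO: blanks encode unavailability and round trips are identity", {
  sk <- as_skims(tibble::tibble(
    zone_id = c("A", "A"), resource_id = c("p1", "p2"),
    t_auto = c(10, 3), t_transit_iv = c(NA, 8), wt = c(NA, 7.5),
    at = c(NA, 4), t_walk = c(55, NA), d_walk = c(2.1, NA)
  ))
  expect_false(sk$avail_transit[1])
  expect_true(sk$avail_transit[2])
  expect_false(sk$avail_walk[2])

  path <- withr::local_tempfile(fileext = ".csv")
  write_skims(sk, path)
  sk2 <- read_skims(path)
  expect_equal(as.data.frame(sk2), as.data.frame(sk))

  # random skims round trip bit for bit
  set.seed(5)
  z <- tiny_zones(4); p <- tiny_parks(3)
  rnd <- auto_skims(z, p, matrix(runif(12, 1, 30), 4, 3))
  write_skims(rnd, path)
  expect_equal(as.data.frame(read_skims(path)), as.data.frame(rnd))
})

test_that("pair lookup is total: absent pairs report full unavailability", {
  sk <- one_pair_skim(t_auto = 10)
  hit <- skim_lookup(sk, "A", "p1")
  expect_equal(hit$t_auto, 10)
  miss <- skim_lookup(sk, "A", "p999")
  expect_false(any(miss$avail_auto, miss$avail_transit, miss$avail_walk))
  expect_true(all(is.na(miss[skim_value_cols()])))
})

test_that("skims reject negative components and duplicate pairs", {
  expect_error(one_pair_skim(t_auto = -1), class = "utilaccess_validation_error")
  expect_error(as_skims(tibble::tibble(
    zone_id = c("A", "A"), resource_id = c("p1", "p1"),
    t_auto = 1, t_transit_iv = NA, wt = NA, at = NA,
    t_walk = NA, d_walk = NA
  )), class = "utilaccess_validation_error")
})

test_that("flow tables validate counts and resolve ids", {
  z <- tiny_zones(2); p <- tiny_parks(2)
  fl <- as_flows(tibble::tibble(zone_id = "A", resource_id = "p1", count = 3),
                 z, p)
  expect_equal(fl$count, 3)
  expect_error(as_flows(tibble::tibble(zone_id = "Z", resource_id = "p1",
                                       count = 3), z, p),
               class = "utilaccess_validation_error")
  expect_error(as_flows(tibble::tibble(zone_id = "A", resource_id = "p1",
                                       count = 1.5)),
               class = "utilaccess_validation_error")
  path <- withr::local_tempfile(fileext = ".csv")
  write_flows(fl, path)
  expect_equal(as.data.frame(read_flows(path)), as.data.frame(fl))
})
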