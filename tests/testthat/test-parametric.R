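test_that("geometric shares hit the evenness target within 1e-6", {
  for (ev in c(0.7, 0.8, 0.9)) {
    p <- geometric_shares(10, ev)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(diff(p) < 0))
    H <- -sum(p * log(p))
    expect_equal(H / log(10), ev, tolerance = 1e-6)
  }
  expect_equal(geometric_shares(6, 1), rep(1 / 6, 6))
  expect_equal(geometric_shares(1, 0.5), 1)
})

test_that("unachievable evenness/richness combinations are rejected", {
  # strongly uneven 10-type community forces the smallest share below 0.1%
  expect_error(geometric_shares(10, 0.2), "parameter error")
  expect_error(parametric_scenario(evenness = 1.5), "evenness")
  expect_error(parametric_scenario(richness = 40), "richness")
  expect_error(parametric_scenario(turnover_per_step = 2), "turnover_per_step")
})

test_that("generated fields recover the prescribed richness exactly", {
  g <- make_grid(lat = c(-10, 10), lon = c(0, 90))
  sc <- parametric_scenario(n_types = 8, richness = 5, evenness = 0.8,
                            turnover_per_step = 0.2)
  f <- generate_parametric(sc, g, years = 2001:2006, seed = 2)
  r <- richness(f)
  expect_true(all(r$value == 5))
})

test_that("generated fields recover the prescribed evenness to 1e-6", {
  g <- make_grid(lat = 0, lon = 0)
  sc <- parametric_scenario(n_types = 10, richness = 6, evenness = 0.75)
  f <- generate_parametric(sc, g, years = 2001:2005, seed = 3)
  ev <- evenness(f)
  expect_true(all(abs(ev$value - 0.75) < 1e-6))
})

test_that("per-year richness and evenness profiles are honoured", {
  g <- make_grid(lat = 0, lon = 0)
  s_t <- c(6, 6, 4, 4)
  e_t <- c(0.9, 0.8, 0.8, 0.7)
  sc <- parametric_scenario(n_types = 12, richness = s_t, evenness = e_t)
  f <- generate_parametric(sc, g, years = 2001:2004, seed = 5)
  expect_equal(richness(f)$value, s_t)
  expect_equal(evenness(f)$value, e_t, tolerance = 1e-6)
})

test_that("replacement turnover is exactly 2k/(s + k) between steps", {
  # replacing k of s present types gives gains = losses = k and union = s + k,
  # so the consecutive-step turnover is deterministic even though which types
  # move is random
  g <- make_grid(lat = c(0, 20), lon = 0)
  s <- 10; frac <- 0.3; k <- ceiling(frac * s)
  sc <- parametric_scenario(n_types = 35, richness = s, evenness = 0.8,
                            turnover_per_step = frac)
  f <- generate_parametric(sc, g, years = 2001:2006, seed = 8)
  for (y in 2001:2005) {
    t <- community_turnover(f, c(y, y), c(y + 1, y + 1))
    expect_equal(t$value, rep(2 * k / (s + k), 2), tolerance = 1e-12)
  }
})

test_that("zero replacement keeps the presence set fixed", {
  g <- make_grid(lat = 0, lon = 0)
  sc <- parametric_scenario(n_types = 8, richness = 5, evenness = 0.8,
                            turnover_per_step = 0)
  f <- generate_parametric(sc, g, years = 2001:2010, seed = 9)
  t <- community_turnover(f, c(2001, 2001), c(2010, 2010))
  expect_equal(t$value, 0)
})

test_that("total biomass follows the prescribed trend", {
  g <- make_grid(lat = 0, lon = 0)
  trend <- seq(1, 0.5, length.out = 4)
  sc <- parametric_scenario(n_types = 8, richness = 4, evenness = 0.9,
                            total_biomass = 200, total_biomass_trend = trend)
  f <- generate_parametric(sc, g, years = 2001:2004, seed = 10)
  tot <- total_phyto_biomass(f)
  expect_equal(tot$value, 200 * trend, tolerance = 1e-9)
})

test_that("generation is deterministic in the seed", {
  g <- make_grid(lat = c(-10, 10), lon = c(0, 90))
  sc <- parametric_scenario(n_types = 8, richness = 5, evenness = 0.8,
                            turnover_per_step = 0.2)
  f1 <- generate_parametric(sc, g, years = 2001:2004, seed = 7)
  f2 <- generate_parametric(sc, g, years = 2001:2004, seed = 7)
  f3 <- generate_parametric(sc, g, years = 2001:2004, seed = 8)
  expect_identical(f1$values, f2$values)
  expect_false(identical(f1$values, f3$values))
})

test_that("the default 35-type pool attaches the full registry", {
  g <- make_grid(lat = 0, lon = 0)
  sc <- parametric_scenario(n_types = 35, richness = 10, evenness = 0.8)
  f <- generate_parametric(sc, g, years = 2001, seed = 1)
  expect_equal(nrow(f$registry), 51)
  zoo <- which(f$registry$trophic_role == "zooplankton")
  expect_true(all(f$values[, , , zoo] == 0))
})

test_that("world assembly requires full latitude coverage and obeys seeds", {
  g <- make_grid(lat = c(-30, 0, 30), lon = c(0, 90))
  sc <- parametric_scenario(n_types = 8, richness = 4, evenness = 0.9)
  bands_partial <- list(list(lat_min = -90, lat_max = 10, scenario = sc))
  expect_error(generate_world(bands_partial, g, years = 2001:2002),
               "no scenario")
  bands <- list(list(lat_min = -90, lat_max = 90, scenario = sc))
  w1 <- generate_world(bands, g, years = 2001:2002, seed = 3)
  w2 <- generate_world(bands, g, years = 2001:2002, seed = 3)
  expect_identical(w1$values, w2$values)
  # noise preserves prescribed richness/evenness in expectation but the field
  # itself must differ from the noise-free one
  w0 <- generate_world(bands, g, years = 2001:2002, seed = 3, noise_sigma = 0)
  expect_false(identical(w1$values, w0$values))
  expect_true(all(richness(w0)$value == 4))
})
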