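make_metric <- function(grid, values, name = "m") {
  tb <- as_tibble(grid)[c("lat", "lon")]
  tb$value <- values
  metric_field(tb, metric_name = name, grid = grid)
}

test_that("percent change follows 100 (end - base) / base, never infinite", {
  g <- make_grid(lat = c(0, 30, 60), lon = 0)
  base <- make_metric(g, c(10, 0, NA))
  end <- make_metric(g, c(15, 5, 2))
  pc <- percent_change(base, end)
  expect_equal(pc$value, c(50, NA, NA))
  expect_equal(attr(pc, "units"), "%")
  g2 <- make_grid(lat = c(0, 30), lon = 0)
  expect_error(percent_change(base, make_metric(g2, c(1, 2))), "same grid")
})

test_that("area fractions are cosine-latitude weighted", {
  # two equal-extent cells at 0 and 60 degrees: weights 1 and 0.5, so a
  # decline confined to the equatorial cell covers 2/3 of the area
  g <- make_grid(lat = c(0, 60), lon = 0)
  m <- make_metric(g, c(-1, 1))
  dec <- area_fraction(m, "decline")
  expect_equal(dec$fraction, 2 / 3, tolerance = 1e-12)
  expect_equal(dec$n_cells_valid, 2)
  inc <- area_fraction(m, "increase")
  expect_equal(inc$fraction, 1 / 3, tolerance = 1e-12)
})

test_that("decline and increase fractions are strict and complementary", {
  g <- make_grid(lat = seq(-60, 60, by = 30), lon = c(0, 90))
  set.seed(31)
  v <- rnorm(10)
  m <- make_metric(g, v)
  dec <- area_fraction(m, "decline")$fraction
  inc <- area_fraction(m, "increase")$fraction
  expect_equal(dec + inc, 1, tolerance = 1e-12)   # no exact zeros drawn
  # an exact zero counts as neither decline nor increase
  v0 <- v; v0[1] <- 0
  m0 <- make_metric(g, v0)
  expect_lt(area_fraction(m0, "decline")$fraction +
            area_fraction(m0, "increase")$fraction, 1)
})

test_that("undefined cells leave both numerator and denominator", {
  g <- make_grid(lat = c(0, 30, 60), lon = 0)
  # NA at 60N: fraction computed over the remaining two cells only
  m <- make_metric(g, c(-1, 1, NA))
  w <- cos(c(0, 30) * pi / 180)
  expect_equal(area_fraction(m, "decline")$fraction, w[1] / sum(w),
               tolerance = 1e-12)
  expect_equal(area_fraction(m, "decline")$n_cells_valid, 2)
  m_all_na <- make_metric(g, c(NA, NA, NA))
  expect_error(area_fraction(m_all_na, "decline"), "no valid cells")
})

test_that("below/above conditions need a cut point and report it", {
  g <- make_grid(lat = c(0, 60), lon = 0)
  m <- make_metric(g, c(2, 10))
  expect_error(area_fraction(m, "below"), "value")
  r <- area_fraction(m, "below", value = 5)
  expect_equal(r$fraction, 2 / 3, tolerance = 1e-12)
  expect_equal(r$condition, "below 5")
})

test_that("latitude bands are half-open [south, north)", {
  g <- make_grid(lat = c(-40, 0, 23, 55), lon = 0)
  rm <- region_mask(g, "band", south = 0, north = 55)
  expect_equal(rm$in_region, c(FALSE, TRUE, TRUE, FALSE))
  nt <- region_mask(g, "n_temperate")
  expect_equal(nt$in_region, c(FALSE, FALSE, TRUE, FALSE))
  pe <- region_mask(g, "polar_or_equatorial")
  expect_equal(pe$in_region, c(FALSE, TRUE, FALSE, TRUE))
  st <- region_mask(g, "subtropics")
  expect_equal(st$in_region, c(TRUE, FALSE, TRUE, FALSE))
  so <- region_mask(g, "southern_ocean")
  expect_equal(so$in_region, c(FALSE, FALSE, FALSE, FALSE))
  so2 <- region_mask(make_grid(lat = c(-50, -40), lon = 0), "southern_ocean")
  expect_equal(so2$in_region, c(TRUE, FALSE))
})

test_that("region masks exclude land", {
  g <- make_grid(lat = c(0, 30), lon = 0,
                 ocean_mask = matrix(c(TRUE, FALSE), 2, 1))
  rm <- region_mask(g, "global")
  expect_equal(rm$in_region, c(TRUE, FALSE))
})

test_that("summary report runs the whole pipeline and writes CSV", {
  f <- preset_field("tiny", seed = 4)
  cfg <- default_report_config()
  cfg <- cfg[cfg$region != "southern_ocean", ]   # tiny grid stops at 30S
  run <- function() {
    summary_report(f, cfg,
                   base_period = c(2005, 2008), end_period = c(2011, 2014),
                   early_pair = list(c(2005, 2006), c(2007, 2008)),
                   late_pair = list(c(2011, 2012), c(2013, 2014)))
  }
  rows <- run()
  expect_equal(nrow(rows), nrow(cfg))
  expect_true(all(rows$fraction >= 0 & rows$fraction <= 1))
  expect_identical(rows, run())                 # deterministic re-run
  csv <- withr::local_tempfile(fileext = ".csv")
  summary_report(f, cfg,
                 base_period = c(2005, 2008), end_period = c(2011, 2014),
                 early_pair = list(c(2005, 2006), c(2007, 2008)),
                 late_pair = list(c(2011, 2012), c(2013, 2014)),
                 csv_path = csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(back$fraction, rows$fraction, tolerance = 1e-12)
})
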