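# Frozen closed-form values:
#   H(0.5, 0.25, 0.25) = 1.5 ln 2 = 1.0397207708399179
#   evenness            = 1.5 ln 2 / ln 3 = 0.946394630...
#   H(4 equal shares)   = ln 4 = 1.3862943611198906

test_that("presence uses the 0.1% share threshold, boundary inclusive", {
  f <- cell_field(matrix(c(899, 100, 1), nrow = 1))  # shares 0.899, 0.1, 0.001
  p <- presence(f)
  expect_equal(as.vector(p$values[1, 1, 1, ]), c(TRUE, TRUE, TRUE))
  f2 <- cell_field(matrix(c(10, 5, 0.001), nrow = 1))  # third share ~7e-5
  expect_equal(as.vector(presence(f2)$values[1, 1, 1, ]),
               c(TRUE, TRUE, FALSE))
  # zero-biomass cell: nothing present (share 0 is not presence even at thr 0)
  f0 <- cell_field(matrix(0, nrow = 1, ncol = 3))
  expect_equal(as.vector(presence(f0, threshold_fraction = 0)$values),
               c(FALSE, FALSE, FALSE))
  expect_error(presence(f, threshold_fraction = 1), "threshold")
  expect_error(presence(f, threshold_fraction = -0.1), "threshold")
})

test_that("richness counts types above the threshold; land is NA", {
  g <- make_grid(lat = c(0, 20), lon = 0,
                 ocean_mask = matrix(c(TRUE, FALSE), 2, 1))
  reg <- toy_registry(3)
  vals <- array(NA_real_, dim = c(1, 2, 1, 3))
  vals[1, 1, 1, ] <- c(10, 5, 0.001)
  f <- biomass_field(vals, 2001, g, reg)
  r <- richness(f)
  expect_equal(r$value, c(2, NA))
  expect_equal(attr(r, "metric_name"), "richness")
})

test_that("Shannon and evenness match the direct-formula oracle to 1e-9", {
  f <- cell_field(matrix(c(0.5, 0.25, 0.25), nrow = 1))
  expect_equal(shannon(f)$value, 1.0397207708399179, tolerance = 1e-12)
  expect_equal(shannon(f)$value, oracle_diversity(c(0.5, 0.25, 0.25))$shannon,
               tolerance = 1e-9)
  expect_equal(evenness(f)$value, 1.5 * log(2) / log(3), tolerance = 1e-12)
  f4 <- cell_field(matrix(rep(2.5, 4), nrow = 1))
  expect_equal(shannon(f4)$value, log(4), tolerance = 1e-12)
  expect_equal(evenness(f4)$value, 1, tolerance = 1e-12)
})

test_that("single-type and empty communities: H = 0, evenness undefined", {
  f1 <- cell_field(matrix(c(5, 0, 0), nrow = 1))
  expect_equal(richness(f1)$value, 1)
  expect_equal(shannon(f1)$value, 0)
  expect_true(is.na(evenness(f1)$value))
  f0 <- cell_field(matrix(0, nrow = 1, ncol = 3))
  expect_equal(richness(f0)$value, 0)
  expect_equal(shannon(f0)$value, 0)
  expect_true(is.na(evenness(f0)$value))
})

test_that("shares are renormalised over included types in the Shannon formula", {
  # third type sits below the threshold: H must come from the other two,
  # renormalised to sum to one
  b <- c(0.7, 0.2995, 0.0005)
  f <- cell_field(matrix(b, nrow = 1))
  expect_equal(richness(f)$value, 2)
  expect_equal(shannon(f)$value, oracle_diversity(b)$shannon, tolerance = 1e-9)
  p <- b[1:2] / sum(b[1:2])
  expect_equal(shannon(f)$value, -sum(p * log(p)), tolerance = 1e-12)
})

test_that("diversity metrics are invariant to biomass rescaling", {
  set.seed(42)
  m <- matrix(runif(5 * 6), nrow = 5)
  f1 <- cell_field(m)
  f2 <- cell_field(m * 1e4)
  expect_equal(shannon(f1)$value, shannon(f2)$value, tolerance = 1e-12)
  expect_equal(richness(f1)$value, richness(f2)$value)
  expect_equal(evenness(f1)$value, evenness(f2)$value, tolerance = 1e-12)
})

test_that("richness is non-increasing in the threshold (property)", {
  set.seed(7)
  for (rep in 1:20) {
    b <- rexp(8)^3
    f <- cell_field(matrix(b, nrow = 1))
    r <- vapply(c(0, 0.001, 0.01, 0.1),
                function(thr) richness(f, threshold_fraction = thr)$value,
                numeric(1))
    expect_true(all(diff(r) <= 0))
  }
})

test_that("random communities match the oracle at every threshold", {
  set.seed(99)
  for (rep in 1:25) {
    b <- rexp(10)^2
    thr <- sample(c(0.001, 0.01, 0.05), 1)
    f <- cell_field(matrix(b, nrow = 1))
    o <- oracle_diversity(b, thr)
    expect_equal(richness(f, threshold_fraction = thr)$value, o$richness)
    expect_equal(shannon(f, threshold_fraction = thr)$value, o$shannon,
                 tolerance = 1e-9)
    ev <- evenness(f, threshold_fraction = thr)$value
    if (is.na(o$evenness)) expect_true(is.na(ev)) else
      expect_equal(ev, o$evenness, tolerance = 1e-9)
  }
})

test_that("zooplankton biomass never enters diversity metrics", {
  reg <- toy_registry(3, n_zoo = 2)
  g <- make_grid(lat = 0, lon = 0)
  vals <- array(0, dim = c(1, 1, 1, 5))
  vals[1, 1, 1, ] <- c(1, 1, 1, 500, 500)
  f <- biomass_field(vals, 2001, g, reg)
  expect_equal(richness(f)$value, 3)
  expect_equal(shannon(f)$value, log(3), tolerance = 1e-12)
})

test_that("appearance and disappearance count threshold crossings per group", {
  reg <- default_type_registry()
  g <- make_grid(lat = 0, lon = 0)
  dia <- which(reg$group == "diatom")
  cocco <- which(reg$group == "coccolithophore")
  base <- array(0, dim = c(1, 1, 1, nrow(reg)))
  end <- base
  # baseline: two diatoms and one coccolithophore present
  base[1, 1, 1, dia[1:2]] <- c(500, 500)
  base[1, 1, 1, cocco[1]] <- 10
  # end: first diatom persists, second drops below threshold, two new diatoms
  # appear; the coccolithophore persists
  end[1, 1, 1, dia[1]] <- 600
  end[1, 1, 1, dia[2]] <- 0.0001       # share ~1e-7, below threshold
  end[1, 1, 1, dia[3:4]] <- c(200, 200)
  end[1, 1, 1, cocco[1]] <- 10
  fb <- biomass_field(base, 2001, g, reg)
  fe <- biomass_field(end, 2001, g, reg)
  ad <- appearance_disappearance(fb, fe, "diatom")
  expect_equal(ad$appearance$value, 2)
  expect_equal(ad$disappearance$value, 1)
  ad2 <- appearance_disappearance(fb, fe, "coccolithophore")
  expect_equal(ad2$appearance$value, 0)
  expect_equal(ad2$disappearance$value, 0)
  expect_error(appearance_disappearance(fb, fe, "krill"), "unknown")
  # identical fields: no crossings in any group
  ad3 <- appearance_disappearance(fb, fb, "diatom")
  expect_equal(ad3$appearance$value, 0)
  expect_equal(ad3$disappearance$value, 0)
})

test_that("appearance counts are bounded by the group size", {
  reg <- default_type_registry()
  g <- make_grid(lat = 0, lon = 0)
  dia <- which(reg$group == "diatom")
  base <- array(0, dim = c(1, 1, 1, nrow(reg)))
  base[1, 1, 1, which(reg$group == "prokaryote")[1]] <- 1
  end <- array(0, dim = c(1, 1, 1, nrow(reg)))
  end[1, 1, 1, dia] <- 1               # all 11 diatoms appear
  fb <- biomass_field(base, 2001, g, reg)
  fe <- biomass_field(end, 2001, g, reg)
  ad <- appearance_disappearance(fb, fe, "diatom")
  expect_equal(ad$appearance$value, 11)
  expect_equal(ad$disappearance$value, 0)
})
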