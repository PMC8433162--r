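test_that("feeding kernel is triangular in log ratio on [5, 15], peak at 10", {
  expect_equal(feeding_kernel(10, 1), 1)          # preferred ratio
  expect_equal(feeding_kernel(5, 1), 0)           # range edges excluded
  expect_equal(feeding_kernel(15, 1), 0)
  expect_equal(feeding_kernel(4, 1), 0)           # outside the range
  expect_equal(feeding_kernel(20, 1), 0)
  expect_equal(feeding_kernel(1, 1), 0)           # same-size prey ignored
  # strictly between edge and peak: linear in log(ratio)
  r <- exp(seq(log(5), log(10), length.out = 7))
  k <- feeding_kernel(r, 1)
  expect_equal(k, (log(r) - log(5)) / (log(10) - log(5)), tolerance = 1e-12)
  expect_true(all(feeding_kernel(exp(runif(50, 0, 4)), 1) >= 0))
  expect_true(all(feeding_kernel(exp(runif(50, 0, 4)), 1) <= 1))
})

test_that("half-saturation increases strictly with cell size", {
  sc <- sim_scenario(years = 2001:2002)
  o <- order(sc$esd_phyto)
  d_esd <- diff(sc$esd_phyto[o])
  d_kn <- diff(sc$k_N[o])
  expect_true(all(d_kn[d_esd > 0] > 0))           # smaller = higher affinity
  expect_true(all(abs(d_kn[d_esd == 0]) < 1e-12)) # equal size = equal k_N
  expect_error(sim_scenario(years = 2001:2002, k_N_exp = -0.5),
               "k_N must increase")
})

test_that("maximum growth rate peaks near 3 um", {
  sc <- sim_scenario(years = 2001:2002)
  at_peak <- which.min(abs(sc$esd_phyto - 3))
  expect_equal(max(sc$mu_max), sc$mu_max[at_peak])
  expect_lt(sc$mu_max[which.max(sc$esd_phyto)], max(sc$mu_max))
})

test_that("closed-system total nitrogen is conserved to integrator tolerance", {
  sc <- sim_scenario(toy_registry(3, n_zoo = 2), years = 2001:2003,
                     nutrient_supply = 0, recycle = 1, spinup_years = 0,
                     extinction_floor = 0)
  sim <- simulate_cell(sc)
  total0 <- sc$N0 + sum(sc$P0) + sum(sc$Z0)
  total1 <- sim$N_final + sum(sim$P_final) + sum(sim$Z_final)
  expect_equal(total1, total0, tolerance = 1e-12)
})

test_that("single-type chemostat matches the closed-form N*", {
  # at steady state mu_max a(T) N/(N + k_N) = m_P, so
  # N* = k_N m_P / (mu_max a(T) - m_P), independent of supply and recycling
  run <- function(temp) {
    sc <- sim_scenario(toy_registry(1), years = 2001:2002,
                       nutrient_supply = 0.05, temperature = temp,
                       spinup_years = 60)
    list(sc = sc, sim = simulate_cell(sc))
  }
  a <- run(20)
  nstar <- function(sc, temp) {
    aT <- exp(sc$E_a * (temp - sc$T_ref))
    sc$k_N * sc$m_P / (sc$mu_max * aT - sc$m_P)
  }
  expect_gt(sum(a$sim$P_final), 0)                  # the type survived
  expect_equal(a$sim$N_final, nstar(a$sc, 20), tolerance = 1e-3)
  # warming raises realised growth, so the equilibrium nutrient drops
  b <- run(26)
  expect_equal(b$sim$N_final, nstar(b$sc, 26), tolerance = 1e-3)
  expect_lt(b$sim$N_final, a$sim$N_final)
})

test_that("constant forcing reaches a steady state", {
  sc <- sim_scenario(toy_registry(4, n_zoo = 2), years = 2001:2010,
                     spinup_years = 60)
  g <- glance(simulate_cell(sc))
  expect_lt(g$rel_change_final_year, 1e-6)
})

test_that("the integration is stable under timestep halving", {
  sc <- sim_scenario(toy_registry(2, n_zoo = 1), years = 2001:2003,
                     spinup_years = 10)
  chk <- check_dt_stability(sc)
  expect_true(chk$stable)
  expect_lt(chk$rel_diff, 0.01)
})

test_that("biomass stays nonnegative and the extinction floor bites", {
  # starve the community: zero supply, open recycling -> types die out
  sc <- sim_scenario(toy_registry(3, n_zoo = 1), years = 2001:2020,
                     nutrient_supply = 0, recycle = 0, N0 = 0.01,
                     spinup_years = 0)
  sim <- simulate_cell(sc)
  expect_true(all(sim$phyto >= 0))
  expect_true(all(sim$zoo >= 0))
  expect_true(all(sim$nutrient >= 0))
  # with the default floor, dying types reach exactly zero, not 1e-300
  expect_true(any(sim$P_final == 0))
})

test_that("simulation output is tidy and deterministic", {
  sc <- sim_scenario(toy_registry(2, n_zoo = 1), years = 2001:2003,
                     spinup_years = 5)
  s1 <- simulate_cell(sc)
  s2 <- simulate_cell(sc)
  expect_identical(s1$phyto, s2$phyto)
  td <- tidy(s1)
  expect_setequal(unique(td$compartment),
                  c("phytoplankton", "zooplankton", "nutrient"))
  expect_equal(nrow(td), 3 * (2 + 1) + 3)   # 3 years x 3 types + nutrient
  expect_equal(td$biomass[td$compartment == "phytoplankton" &
                            td$year == 2003],
               unname(s1$phyto[3, ]))
})

test_that("scenario forcing vectors must be scalar or one per year", {
  expect_error(sim_scenario(toy_registry(1), years = 2001:2004,
                            nutrient_supply = c(0.1, 0.2)),
               "nutrient_supply")
  sc <- sim_scenario(toy_registry(1), years = 2001:2004,
                     temperature = c(10, 12, 14, 16))
  expect_equal(sc$temperature, c(10, 12, 14, 16))
})
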