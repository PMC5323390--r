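test_that("cell-to-biomass conversion follows the biovolume arithmetic", {
  const <- budget_constants()
  expect_equal(biomass_from_cells(0, const), 0)
  # 1e9 cells * 0.07 um3 * 3e-13 g/um3 = 21 ug C -> /12.011 = 1.748 umol
  expect_equal(biomass_from_cells(1e9, const), 21 / 12.011,
               tolerance = 1e-12)
  expect_equal(biomass_from_cells(4e9, const), 4 * 21 / 12.011,
               tolerance = 1e-12)
  # linearity
  a <- runif(5, 0, 5e9); b <- runif(5, 0, 5e9)
  expect_equal(biomass_from_cells(a + b, const),
               biomass_from_cells(a, const) + biomass_from_cells(b, const))
  expect_error(biomass_from_cells(-1, const), "non-negative")
})

test_that("added carbon converts to the printed molar concentration", {
  expect_equal(added_C_molar(0.2, 12.011), 16.6514, tolerance = 1e-4)
  expect_equal(added_C_molar(0), 0)
  expect_equal(added_C_molar(12.011, 12.011), 1000)
  const <- budget_constants()
  expect_equal(const$added_C_molar,
               const$added_C_mass * 1000 / const$molar_mass_C,
               tolerance = 1e-9)
})

test_that("yield, respiration and percentage columns follow Table-1 arithmetic", {
  const <- budget_constants()
  expect_equal(net_biomass_yield(6.7, 3.9), 2.8)
  expect_equal(net_biomass_yield(5, 5), 0)
  expect_equal(net_biomass_yield(4.5, 3.9), 0.6)
  expect_equal(net_C_respired(6.1, 2.9, const), 3.2)
  expect_equal(net_C_respired(4.9, 2.9, const), 2.0)
  expect_equal(net_C_respired(3, 3, const), 0)
  expect_equal(pct_of_added_C(6.0, const), 36.03, tolerance = 1e-3)
  expect_equal(pct_of_added_C(0, const), 0)
  expect_equal(pct_of_added_C(const$added_C_molar, const), 100)
})

test_that("growth efficiency is the biomass share of total carbon used", {
  expect_equal(growth_efficiency(2.8, 6.0), 46.667, tolerance = 1e-4)
  expect_equal(growth_efficiency(0, 3), 0)
  expect_equal(growth_efficiency(1.1, 2.6), 42.308, tolerance = 1e-4)
  ge <- growth_efficiency(1, 0)
  expect_true(is.na(ge))
  expect_equal(attr(ge, "not_available"), 1L)
})

test_that("duplication time inverts exponential growth", {
  expect_equal(duplication_time(2e9, 4e9, 17), 17)
  expect_equal(duplication_time(1.4e9, 2.3e9, 23), 32.11, tolerance = 1e-3)
  d <- duplication_time(1e9, 1e9, 23)
  expect_true(is.infinite(d))
  expect_equal(attr(d, "no_growth"), 1L)
  expect_error(duplication_time(0, 1e9, 23), "positive")
})

test_that("budget table reproduces derived columns from measured inputs", {
  fx <- table1_frames()
  tab <- build_budget_table(fx$counts, fx$o2)
  rownames(tab) <- tab$treatment
  chi <- tab["CHI", ]
  expect_equal(chi$net_yield, 2.8, tolerance = 1e-9)
  expect_equal(chi$net_C_respired, 3.2, tolerance = 1e-9)
  expect_equal(chi$total_C_used, 6.0, tolerance = 1e-9)
  expect_equal(chi$total_pct, 36.0, tolerance = 0.002)
  expect_equal(chi$growth_efficiency, 46.67, tolerance = 1e-4)
  expect_equal(tab["TWEI", "respired_pct"], 12.01, tolerance = 1e-3)
  expect_equal(tab["MARC", "net_C_respired"], 1.5, tolerance = 1e-9)
  # control row carries NA for treatment-relative columns
  expect_true(is.na(tab["unfed", "net_yield"]))
  expect_true(is.na(tab["unfed", "growth_efficiency"]))
})

test_that("budget table additivity and percentage consistency hold exactly", {
  fx <- table1_frames()
  tab <- build_budget_table(fx$counts, fx$o2)
  ok <- !is.na(tab$total_C_used)
  expect_equal(tab$total_C_used[ok],
               tab$net_yield[ok] + tab$net_C_respired[ok])
  expect_equal(tab$total_pct[ok],
               tab$assimilation_pct[ok] + tab$respired_pct[ok],
               tolerance = 1e-9)
})

test_that("doubling the added carbon halves every percentage column only", {
  fx <- table1_frames()
  t1 <- build_budget_table(fx$counts, fx$o2, budget_constants())
  t2 <- build_budget_table(fx$counts, fx$o2,
                           budget_constants(added_C_mass = 0.4))
  ok <- !is.na(t1$net_yield)
  expect_equal(t2$assimilation_pct[ok], t1$assimilation_pct[ok] / 2)
  expect_equal(t2$respired_pct[ok], t1$respired_pct[ok] / 2)
  expect_equal(t2$total_pct[ok], t1$total_pct[ok] / 2)
  expect_equal(t2$net_yield, t1$net_yield)
  expect_equal(t2$net_C_respired, t1$net_C_respired)
  expect_equal(t2$growth_efficiency, t1$growth_efficiency)
})

test_that("treatments identical to the control give zero yields and respiration", {
  counts <- data.frame(sample = c("u0", "a0", "u", "a"),
                       treatment = c("unfed", "A", "unfed", "A"),
                       day = c(0, 0, 23, 23),
                       cells_per_ml = c(1e9, 1e9, 2e9, 2e9))
  o2 <- data.frame(sample = c("ub", "ab"), treatment = c("unfed", "A"),
                   o2_umol_per_ml = c(3, 3))
  tab <- build_budget_table(counts, o2)
  a <- tab[tab$treatment == "A", ]
  expect_equal(a$net_yield, 0)
  expect_equal(a$net_C_respired, 0)
  expect_error(build_budget_table(counts[counts$treatment == "A", ], o2),
               "unfed")
})

test_that("noise-free synthetic data recovers the configured growth efficiency", {
  cfg <- sim_config(count_cv = 0, fluor_cv = 0, optode_sd = 0, seed = 3)
  geom <- bag_geometry()
  cells <- simulate_growth(cfg)
  oxy <- simulate_bag_oxygen(cfg, geom)
  o2 <- oxygen_uptake_table(oxy, geom, duration = cfg$duration,
                            dilution_factor = cfg$dilution_factor)
  tab <- build_budget_table(cells, o2)
  rownames(tab) <- tab$treatment
  const <- budget_constants()
  for (tr in setdiff(cfg$treatments, "unfed")) {
    yield <- biomass_from_cells(
      cfg$n0_cells * exp(cfg$growth_rate[[tr]] * cfg$duration), const) -
      biomass_from_cells(
        cfg$n0_cells * exp(cfg$growth_rate[["unfed"]] * cfg$duration), const)
    resp <- (cfg$respiration[[tr]] - cfg$respiration[["unfed"]]) *
      cfg$duration * cfg$dilution_factor / 1000
    expect_equal(tab[tr, "growth_efficiency"],
                 yield / (yield + resp) * 100, tolerance = 1e-9)
  }
})
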