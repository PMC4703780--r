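# Chemostat stoichiometry and batch rate estimation.

state <- function(...) {
  args <- list(...)
  base <- list(
    influent_nitrite = 20, influent_nitrate = 1,
    influent_organic_carbon = 37.5, influent_organic_n = 5.3,
    effluent_ammonium = 2.5, effluent_nitrite = 0,
    protein_g_per_l = 0.12, dilution_rate = 0.08, temperature = 10
  )
  utils::modifyList(base, args)
}

test_that("C:N ratio reproduces the worked medium compositions", {
  expect_equal(cn_ratio(state()), 37.5 / 21)
  expect_equal(round(cn_ratio(state()), 1), 1.8)
  expect_equal(cn_ratio(state(influent_organic_carbon = 28)), 28 / 21)
  expect_equal(cn_ratio(state(influent_organic_carbon = 0)), 0)
  expect_error(
    cn_ratio(state(influent_nitrite = 0, influent_nitrate = 0)),
    "undefined"
  )
  # dimensionless: scaling all concentrations changes nothing
  s2 <- state(
    influent_nitrite = 40, influent_nitrate = 2,
    influent_organic_carbon = 75
  )
  expect_equal(cn_ratio(s2), cn_ratio(state()))
})

test_that("nitrogen balance and protein prediction follow the model", {
  s <- state()
  expect_equal(nitrogen_balance(s), 2.8)
  m <- biomass_model()
  # 2.8 mM-N -> 14 mM biomass C -> x formula mass x protein share
  expect_equal(
    protein_from_nitrogen(2.8, m),
    2.8 / 1000 / m$n_to_c * m$formula_mass * m$protein_fraction
  )
  expect_equal(nitrogen_balance(state(effluent_ammonium = 5.3)), 0)
  expect_equal(protein_from_nitrogen(0, m), 0)
  expect_warning(nitrogen_balance(state(effluent_ammonium = 6)), "DNRA")
  # linearity
  expect_equal(
    protein_from_nitrogen(3, m),
    3 * protein_from_nitrogen(1, m)
  )
})

test_that("growth yield inverts the protein conversion", {
  m <- biomass_model()
  expect_equal(growth_yield(0, 28, m), 0)
  y <- growth_yield(0.14, 28, m)
  expect_equal(y, 0.14 / m$protein_fraction / m$formula_mass * 1000 / 28)
  expect_error(growth_yield(1, 10, m), "infeasible")
})

test_that("noise-free chemostats round-trip yield and protein exactly", {
  for (truey in c(0.1, 0.25, 0.4)) {
    sc <- chemostat_scenario(true_yield = truey, noise_sd = 0)
    st <- simulate_chemostat(sc)
    expect_equal(
      growth_yield(st$protein_g_per_l, st$converted_carbon),
      truey,
      tolerance = 1e-9
    )
    expect_equal(
      protein_from_nitrogen(nitrogen_balance(st)),
      st$protein_g_per_l,
      tolerance = 1e-9
    )
  }
  # C and N conservation before noise: influent = effluent + assimilated
  sc <- chemostat_scenario(true_yield = 0.3, noise_sd = 0)
  st <- simulate_chemostat(sc)
  expect_equal(
    st$influent_organic_n,
    st$effluent_ammonium + st$truth$assimilated_n,
    tolerance = 1e-12
  )
  expect_equal(
    st$truth$assimilated_c,
    0.3 * st$converted_carbon,
    tolerance = 1e-12
  )
})

test_that("infeasible nitrogen demand is rejected", {
  expect_error(
    simulate_chemostat(
      chemostat_scenario(influent_organic_n = 0.5, true_yield = 0.9)
    ),
    "infeasible"
  )
})

test_that("medium recipe splits carbon by the stated fractions", {
  r <- medium_recipe(28)
  expect_equal(unname(r), c(12.32, 2.24, 13.44))
  expect_equal(sum(r), 28, tolerance = 1e-9)
  expect_equal(unname(medium_recipe(0)), c(0, 0, 0))
  expect_error(medium_recipe(28, c(0.5, 0.5, 0.1)), "sum to 1")
})

test_that("batch rate is the exact OLS slope with unit conversion", {
  series <- data.frame(time_h = 0:2, concentration_mM = c(1.0, 0.8, 0.6))
  br <- batch_rate(series)
  expect_equal(br$slope_mM_per_h, -0.2, tolerance = 1e-12)
  expect_equal(br$slope_umol_per_l_per_day, -0.2 * 24000, tolerance = 1e-9)

  sim <- simulate_batch(-0.9, n_samples = 7, c0 = 2.0, noise_sd = 0)
  expect_equal(batch_rate(sim)$slope_mM_per_h, -0.9, tolerance = 1e-12)

  expect_error(batch_rate(series[1:2, ]), "3")
  bad <- data.frame(time_h = c(0, 2, 1), concentration_mM = c(1, 2, 3))
  expect_error(batch_rate(bad), "increasing")
})

test_that("the noiseless example series matches hand evaluation", {
  b <- simulate_batch(-1, n_samples = 7, interval_h = 1 / 3, c0 = 0.7,
    noise_sd = 0
  )
  expect_equal(
    b$concentration_mM,
    c(0.7, 0.7 - 1 / 3, 0.7 - 2 / 3, 0, 0, 0, 0),
    tolerance = 1e-12
  )
  expect_true(all(b$clipped[4:7]))
  # seeded repeat is identical
  b1 <- simulate_batch(-0.5, c0 = 1, noise_sd = 0.05, seed = 4L)
  b2 <- simulate_batch(-0.5, c0 = 1, noise_sd = 0.05, seed = 4L)
  expect_identical(b1, b2)
})

test_that("the full mass balance reproduces the enrichment worked example", {
  # 37.5 mM-C over 20+1 mM N; 5.3 mM-N in, 2.5 mM ammonium out
  mb <- mass_balance(state(protein_g_per_l = 0.12))
  expect_equal(round(mb$cn_ratio, 1), 1.8)
  expect_equal(mb$assimilated_n, 2.8)
  expect_equal(mb$predicted_protein, 0.15, tolerance = 0.02 / 0.15)
  out <- capture.output(print(mb))
  expect_true(any(grepl("assimilated N", out)))
})
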