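# Hand-computed oracle values for the indicator arithmetic, plus the
# structural properties (energy identity, price-scale invariance,
# additivity under record splitting).

coefs <- default_coefficients()

test_that("rice equivalent yield follows the price-ratio definition", {
  # Identity case: a single aman crop sold at the household rice price.
  obs <- make_obs(aman = list(grain_yield = 2.0, crop_price = 17000))
  expect_equal(rice_equivalent_yield(obs), 2.0)

  # A non-rice crop at three times the rice price contributes 3x its mass.
  obs <- make_obs(system_label = "MFA",
                  aman = list(grain_yield = 0, crop_price = 17000),
                  rabi = list(grain_yield = 1.0, crop_price = 3 * 17000))
  expect_equal(rice_equivalent_yield(obs), 3.0)

  # Full toy: aman 2.4 t + straw grain-equivalent 0.2 t + mungbean
  # 0.9 t at triple price = 2.4 + 0.2 + 2.7.
  expect_equal(rice_equivalent_yield(toy_mfa_obs()), 5.3)

  bad <- make_obs(rice_price_household = -1)
  expect_error(rice_equivalent_yield(bad), "P_r")
})

test_that("economics sums gross, cost and net returns", {
  zero <- make_obs()
  expect_equal(economics(zero),
               list(gross_returns = 0, cost = 0, net_returns = 0))

  obs <- make_obs(aman = list(grain_yield = 2.4, crop_price = 20000,
                              straw_yield = 2.0, straw_price = 2000,
                              cost_inputs = 12000, cost_labor = 10000,
                              cost_landprep = 5000, cost_irrigation = 3000))
  res <- economics(obs)
  expect_equal(res$gross_returns, 52000)  # 2.4 x 20000 + 2.0 x 2000
  expect_equal(res$cost, 30000)
  expect_equal(res$net_returns, 22000)

  even <- make_obs(aman = list(grain_yield = 5, crop_price = 20000,
                               cost_inputs = 100000))
  expect_equal(economics(even)$net_returns, 0)
})

test_that("agronomic energy input matches hand arithmetic and is linear", {
  expect_equal(agronomic_energy_input(make_obs(), coefs), 0)

  # 100 kg N (60.6 MJ/kg) + 200 person-hours (1.96 MJ/h) = 6.452 GJ.
  obs <- make_obs(aman = list(n_rate = 100, labor_total = 200))
  expect_equal(agronomic_energy_input(obs, coefs), 6.452, tolerance = 1e-9)

  doubled <- make_obs(aman = list(n_rate = 200, labor_total = 400))
  expect_equal(agronomic_energy_input(doubled, coefs),
               2 * agronomic_energy_input(obs, coefs))
})

test_that("total energy production uses grain only, never straw", {
  expect_equal(total_energy_production(make_obs(), coefs), 0)

  # 2.4 t aman grain x 14.7 MJ/kg = 35.28 GJ; straw must not contribute.
  obs <- make_obs(aman = list(grain_yield = 2.4, crop_price = 17000,
                              straw_yield = 5, straw_price = 2000))
  expect_equal(total_energy_production(obs, coefs), 35.28, tolerance = 1e-9)

  with_second <- make_obs(system_label = "MFA",
                          aman = list(grain_yield = 2.4, crop_price = 17000),
                          rabi = list(grain_yield = 0.5, crop_price = 40000))
  expect_gt(total_energy_production(with_second, coefs), 35.28)
})

test_that("net energy yield is a plain difference", {
  expect_equal(net_energy_yield(35.28, 6.452), 28.828)
  expect_equal(net_energy_yield(4, 4), 0)
  expect_equal(net_energy_yield(0, 5), -5)
})

test_that("fertilizer N2O follows the IPCC Tier-1 pathway", {
  expect_equal(n2o_co2e(0), 0)
  # 100 kg N: direct 1.0 + deposition 0.1 + leaching 0.225 kg N2O-N,
  # x 44/28 x 265.
  expect_equal(n2o_co2e(100), 551.76785714285713, tolerance = 1e-9)
  expect_equal(n2o_co2e(2 * 137), 2 * n2o_co2e(137))
  expect_equal(n2o_co2e(c(0, 100)), c(0, 551.76785714285713))
})

test_that("partial GHG footprint divides emissions by energy production", {
  # Zero inputs, positive yield: zero footprint.
  clean <- make_obs(aman = list(grain_yield = 2.0, crop_price = 17000))
  expect_equal(partial_ghg_footprint(clean, coefs), 0)

  # 2.4 t aman + 100 kg N: (100 x 4.8 + 551.7679) / 35.28 kg CO2e/GJ.
  obs <- make_obs(aman = list(grain_yield = 2.4, crop_price = 17000,
                              n_rate = 100))
  expect_equal(partial_ghg_footprint(obs, coefs),
               (100 * 4.8 + 551.76785714285713) / 35.28, tolerance = 1e-9)

  # Zero production: undefined, not 0 or Inf.
  expect_true(is.na(partial_ghg_footprint(make_obs(aman = list(n_rate = 10)),
                                          coefs)))

  # Adding a zero-emission crop with positive yield dilutes the footprint.
  diluted <- make_obs(system_label = "MFA",
                      aman = list(grain_yield = 2.4, crop_price = 17000,
                                  n_rate = 100),
                      rabi = list(grain_yield = 0.5, crop_price = 40000))
  expect_lt(partial_ghg_footprint(diluted, coefs),
            partial_ghg_footprint(obs, coefs))
})

test_that("efficiency indicators and undefined-denominator masks", {
  ind <- compute_indicators(toy_survey(), coefs)
  expect_equal(nrow(ind), 3)

  # pnp on the frozen toy: TEP 35.28 GJ over 31 kg N.
  obs <- make_obs(aman = list(grain_yield = 2.4, crop_price = 17000,
                              n_rate = 31))
  one <- compute_indicators(obs, coefs)
  expect_equal(one$pnp, 35.28 / 31, tolerance = 1e-9)
  expect_equal(one$pnp, 1.138, tolerance = 1e-3)

  # Zero denominators are NA, the row is retained.
  zero <- compute_indicators(
    make_obs(aman = list(grain_yield = 1, crop_price = 17000)), coefs)
  expect_equal(nrow(zero), 1)
  expect_true(is.na(zero$pnp))
  expect_true(is.na(zero$pkp))
  expect_true(is.na(zero$bcr))
  expect_true(is.na(zero$hlep))
  expect_false(is.na(zero$ghg_footprint))

  # bcr = 1 when gross equals cost; energy efficiency 1 when NEY = AEI.
  even <- compute_indicators(
    make_obs(aman = list(grain_yield = 5, crop_price = 20000,
                         cost_inputs = 100000)), coefs)
  expect_equal(even$bcr, 1)
  # No energy inputs at all: efficiency is masked, not infinite.
  expect_true(is.na(even$energy_efficiency))
})

test_that("grouped engine agrees with the per-observation operations", {
  survey <- generate_survey(small_config(15), seed = 11)
  ind <- compute_indicators(survey, coefs)
  for (i in sample(nrow(ind), 5)) {
    obs <- survey[survey$household_id == ind$household_id[i] &
                    survey$system_label == ind$system_label[i], ]
    expect_equal(ind$rey[i], rice_equivalent_yield(obs))
    expect_equal(ind$aei[i], agronomic_energy_input(obs, coefs))
    expect_equal(ind$tep[i], total_energy_production(obs, coefs))
    eco <- economics(obs)
    expect_equal(ind$net_returns[i], eco$net_returns)
    expect_equal(ind$ghg_footprint[i], partial_ghg_footprint(obs, coefs))
  }
})

test_that("energy identity, price invariance and additivity hold", {
  survey <- generate_survey(small_config(60), seed = 21)
  ind <- compute_indicators(survey, coefs)
  expect_equal(ind$tep, ind$ney + ind$aei, tolerance = 1e-12)
  ok <- !is.na(ind$energy_efficiency)
  expect_equal(ind$tep[ok] / ind$aei[ok], ind$energy_efficiency[ok] + 1,
               tolerance = 1e-12)

  # REY is invariant to rescaling all prices by a common factor.
  scaled <- survey
  for (cl in c("crop_price", "straw_price", "rice_price_household")) {
    scaled[[cl]] <- scaled[[cl]] * 3.7
  }
  expect_equal(compute_indicators(scaled, coefs)$rey, ind$rey,
               tolerance = 1e-12)

  # Splitting every record into two half-rate records leaves the
  # per-observation aggregates unchanged (prices are intensive).
  obs <- toy_mfa_obs()
  obs$n_rate[1] <- 40
  obs$labor_total[3] <- 220
  obs$labor_hired[3] <- 18
  obs$cost_inputs[1] <- 9000
  half <- obs
  ext_cols <- c("grain_yield", "straw_yield", "n_rate", "p_rate", "k_rate",
                "pesticide", "fuel", "labor_total", "labor_hired",
                "cost_inputs", "cost_labor", "cost_landprep",
                "cost_irrigation")
  for (cl in ext_cols) half[[cl]] <- half[[cl]] / 2
  split_obs <- dplyr::bind_rows(half, half)
  expect_equal(rice_equivalent_yield(split_obs), rice_equivalent_yield(obs))
  expect_equal(agronomic_energy_input(split_obs, coefs),
               agronomic_energy_input(obs, coefs))
  expect_equal(total_energy_production(split_obs, coefs),
               total_energy_production(obs, coefs))
  expect_equal(economics(split_obs), economics(obs))
  expect_equal(partial_ghg_footprint(split_obs, coefs),
               partial_ghg_footprint(obs, coefs))
})

test_that("USD view rescales economics without touching BDT storage", {
  ind <- compute_indicators(toy_survey(), coefs)
  usd <- economics_in_usd(ind, coefs)
  expect_equal(usd$gross_returns, ind$gross_returns * coefs$usd_per_bdt)
  expect_equal(usd$net_returns, usd$gross_returns - usd$cost)
})
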