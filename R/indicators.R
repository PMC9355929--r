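# Household x system indicator engine.
#
# All indicators are computed at the cropping-system level over a full
# annual cycle (rabi, kharif-1, kharif-2), per hectare. Energy units GJ/ha,
# economics BDT/ha, emissions kg CO2e/ha. Undefined indicators (zero
# denominators) are NA, never 0 or Inf, and are excluded listwise per
# indicator downstream.

# Per-record contributions to every system aggregate. `records` must carry
# the survey quantity columns; returns one row per input record.
record_contributions <- function(records, table) {
  crop <- records$crop
  is_rice <- crop %in% croppsi_rice_crops
  # Straw converted to grain-equivalent mass via the straw/grain price ratio
  # (rice only); records with zero grain price contribute no straw term.
  straw_ge <- ifelse(is_rice & records$crop_price > 0,
                     records$straw_yield * records$straw_price / records$crop_price,
                     0)
  yx <- records$grain_yield + straw_ge
  e <- table$energy_per_input
  g <- table$ghg_per_input
  tibble::tibble(
    yx = yx,
    value = yx * records$crop_price,                      # BDT/ha, for REY
    gross = records$grain_yield * records$crop_price +
      ifelse(is_rice, records$straw_yield * records$straw_price, 0),
    cost = records$cost_inputs + records$cost_labor +
      records$cost_landprep + records$cost_irrigation,
    aei_mj = records$n_rate * e[["n"]] + records$p_rate * e[["p2o5"]] +
      records$k_rate * e[["k2o"]] + records$pesticide * e[["pesticide"]] +
      records$fuel * e[["fuel"]] + records$labor_total * table$energy_labor,
    tep_gj = records$grain_yield * grain_energy_factor(crop, table),
    ghg_kg = records$n_rate * g[["n"]] + records$p_rate * g[["p2o5"]] +
      records$k_rate * g[["k2o"]] + records$pesticide * g[["pesticide"]] +
      records$fuel * g[["fuel"]] +
      n2o_co2e(records$n_rate, table$n2o_factors),
    n_kg = records$n_rate,
    k_kg = records$k_rate,
    hired_psd = records$labor_hired
  )
}

#' Rice-equivalent yield of one system observation
#'
#' Sums, over the non-fallow crops of an annual system, yield times the
#' crop/rice price ratio: `sum(Y_x * P_x / P_r)`. For rice crops `Y_x` is
#' grain yield plus straw converted to grain-equivalent mass by the
#' straw/grain price ratio. `P_r` is the household's own aman selling
#' price, so REY is expressed in aman-rice tonnes.
#'
#' @param obs Records of a single household x system (a survey subset).
#' @return REY in t/ha/yr.
#' @export
rice_equivalent_yield <- function(obs) {
  p_r <- obs$rice_price_household[1]
  if (!isTRUE(p_r > 0)) abort("household rice price P_r must be > 0")
  contr <- record_contributions(obs, null_energy_table())
  sum(contr$value) / p_r
}

# Coefficient stand-in for operations that only need prices/yields.
null_energy_table <- function() {
  structure(list(
    energy_per_input = setNames(rep(1, length(input_kinds)), input_kinds),
    energy_labor = 1, energy_rice_grain = 1,
    energy_grain_by_crop = setNames(rep(1, length(croppsi_crops)), croppsi_crops),
    ghg_per_input = setNames(rep(1, length(input_kinds)), input_kinds),
    n2o_factors = n2o_defaults, usd_per_bdt = 1
  ), class = "croppsi_coefficients")
}

#' Gross returns, cost of cultivation and net returns
#'
#' Gross returns sum yields times unit prices over all crops, including
#' rice straw value. Cost of cultivation sums input, labor, land
#' preparation and irrigation costs. Net returns are the difference.
#'
#' @inheritParams rice_equivalent_yield
#' @return Named list: `gross_returns`, `cost`, `net_returns` (BDT/ha/yr).
#' @export
economics <- function(obs) {
  contr <- record_contributions(obs, null_energy_table())
  gross <- sum(contr$gross)
  cost <- sum(contr$cost)
  list(gross_returns = gross, cost = cost, net_returns = gross - cost)
}

#' Agronomic energy input of one system observation
#'
#' Embedded energy of all agronomic inputs (fertilizer nutrients, pesticide
#' active ingredient, diesel fuel) plus human labor energy
#' (total person-hours times the labor energy factor), summed over all
#' crops of the annual system.
#'
#' @inheritParams rice_equivalent_yield
#' @param table A [croppsi_coefficients][load_coefficients] table.
#' @return AEI in GJ/ha/yr.
#' @export
agronomic_energy_input <- function(obs, table) {
  sum(record_contributions(obs, table)$aei_mj) / 1000
}

#' Total energy production of one system observation
#'
#' Grain yields only (straw energy is deliberately excluded), converted by
#' the rice grain energy factor for rice crops and per-crop factors for
#' non-rice crops.
#'
#' @inheritParams agronomic_energy_input
#' @return TEP in GJ/ha/yr.
#' @export
total_energy_production <- function(obs, table) {
  sum(record_contributions(obs, table)$tep_gj)
}

#' Net energy yield
#'
#' Total energy production minus agronomic energy input; may be negative.
#'
#' @param tep,aei GJ/ha/yr.
#' @return NEY in GJ/ha/yr.
#' @export
net_energy_yield <- function(tep, aei) tep - aei

#' Fertilizer-derived N2O emissions as CO2 equivalents
#'
#' IPCC Tier-1 accounting of direct and indirect N2O from applied
#' fertilizer N: direct emission (EF1), indirect emission of volatilized N
#' re-deposited (FracGASF x EF4) and of leached/runoff N (FracLEACH x EF5).
#' N2O-N is converted to N2O by 44/28 and to CO2e by the N2O global
#' warming potential.
#'
#' @param n_rate Applied fertilizer N, kg N/ha (vectorized).
#' @param factors List with `ef1`, `ef4`, `ef5`, `frac_gasf`, `frac_leach`,
#'   `gwp_n2o`; defaults are the IPCC Tier-1 values.
#' @return kg CO2e/ha.
#' @export
n2o_co2e <- function(n_rate, factors = n2o_defaults) {
  stopifnot(all(n_rate >= 0))
  n2o_n <- n_rate * factors$ef1 +
    n_rate * factors$frac_gasf * factors$ef4 +
    n_rate * factors$frac_leach * factors$ef5
  n2o_n * (44 / 28) * factors$gwp_n2o
}

#' Partial greenhouse-gas footprint of one system observation
#'
#' Embedded emissions of input production and use (fertilizer, pesticide,
#' fuel) plus fertilizer-derived N2O, divided by total energy production.
#' Soil methane from flooded fields is never included (a partial
#' footprint). Undefined (NA) when TEP is zero.
#'
#' @inheritParams agronomic_energy_input
#' @return kg CO2e per GJ of energy production.
#' @export
partial_ghg_footprint <- function(obs, table) {
  contr <- record_contributions(obs, table)
  tep <- sum(contr$tep_gj)
  if (tep <= 0) return(NA_real_)
  sum(contr$ghg_kg) / tep
}

#' Compute all performance indicators per household x system
#'
#' One row per household x system observation with the productivity
#' indicators (rice-equivalent yield, total energy production, economics)
#' and the resource-use efficiency indicators: energy efficiency
#' (NEY/AEI), partial N and K productivity (TEP per kg N or K2O applied
#' over the whole system), benefit-cost ratio (gross/cost), partial GHG
#' footprint (kg CO2e/GJ) and hired-labor energy productivity (TEP per
#' hired person-day). Zero-denominator indicators are NA.
#'
#' @param survey A validated survey tibble ([read_survey()],
#'   [generate_survey()]).
#' @param table A coefficient table; [default_coefficients()] by default.
#' @return A tibble, one row per household x system.
#' @export
compute_indicators <- function(survey, table = default_coefficients()) {
  survey <- validate_survey(survey)
  if (nrow(survey) == 0) {
    return(tibble::tibble(
      household_id = character(0), stratum = character(0),
      system_label = character(0),
      rey = numeric(0), gross_returns = numeric(0), cost = numeric(0),
      net_returns = numeric(0), aei = numeric(0), tep = numeric(0),
      ney = numeric(0), energy_efficiency = numeric(0), pnp = numeric(0),
      pkp = numeric(0), bcr = numeric(0), ghg_footprint = numeric(0),
      hlep = numeric(0)
    ))
  }
  contr <- record_contributions(survey, table)
  dplyr::bind_cols(
    survey[c("household_id", "stratum", "system_label", "rice_price_household")],
    contr
  ) %>%
    group_by(.data$household_id, .data$stratum, .data$system_label) %>%
    summarise(
      rey = sum(.data$value) / .data$rice_price_household[1],
      gross_returns = sum(.data$gross),
      cost = sum(.data$cost),
      aei = sum(.data$aei_mj) / 1000,
      tep = sum(.data$tep_gj),
      ghg_total = sum(.data$ghg_kg),
      n_total = sum(.data$n_kg),
      k_total = sum(.data$k_kg),
      hired_total = sum(.data$hired_psd),
      .groups = "drop"
    ) %>%
    mutate(
      net_returns = .data$gross_returns - .data$cost,
      ney = .data$tep - .data$aei,
      energy_efficiency = ifelse(.data$aei > 0, .data$ney / .data$aei, NA_real_),
      pnp = ifelse(.data$n_total > 0, .data$tep / .data$n_total, NA_real_),
      pkp = ifelse(.data$k_total > 0, .data$tep / .data$k_total, NA_real_),
      bcr = ifelse(.data$cost > 0, .data$gross_returns / .data$cost, NA_real_),
      ghg_footprint = ifelse(.data$tep > 0, .data$ghg_total / .data$tep, NA_real_),
      hlep = ifelse(.data$hired_total > 0, .data$tep / .data$hired_total, NA_real_)
    ) %>%
    select("household_id", "stratum", "system_label", "rey",
           "gross_returns", "cost", "net_returns", "aei", "tep", "ney",
           "energy_efficiency", "pnp", "pkp", "bcr", "ghg_footprint", "hlep")
}

#' Express economic columns in USD
#'
#' Derived view: converts the BDT economics columns of an indicator table
#' to USD at the coefficient table's exchange rate. Values are never stored
#' twice; this returns a new tibble.
#'
#' @param indicators Output of [compute_indicators()].
#' @param table Coefficient table carrying `usd_per_bdt`.
#' @return The tibble with `gross_returns`, `cost`, `net_returns` in USD.
#' @export
economics_in_usd <- function(indicators, table = default_coefficients()) {
  mutate(indicators,
         across(all_of(c("gross_returns", "cost", "net_returns")),
                ~ .x * table$usd_per_bdt))
}
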