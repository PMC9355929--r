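# In-code fixtures shared across the suite.

# One crop-season record with every quantity defaulting to zero.
make_record <- function(household_id = "H1", stratum = "within_polder",
                        system_label = "FFA", season = "kharif2",
                        crop = "aman_rice", rice_price_household = 17000,
                        ...) {
  qty <- list(grain_yield = 0, straw_yield = 0, crop_price = 0,
              straw_price = 0, n_rate = 0, p_rate = 0, k_rate = 0,
              pesticide = 0, fuel = 0, labor_total = 0, labor_hired = 0,
              cost_inputs = 0, cost_labor = 0, cost_landprep = 0,
              cost_irrigation = 0)
  qty <- utils::modifyList(qty, list(...))
  tibble::tibble(household_id = household_id, stratum = stratum,
                 system_label = system_label, season = season, crop = crop,
                 !!!qty, rice_price_household = rice_price_household)
}

# A full household x system observation: rabi crop (or fallow), fallow
# kharif-1, and a kharif-2 aman record.
make_obs <- function(household_id = "H1", system_label = "FFA",
                     stratum = "within_polder", rice_price_household = 17000,
                     aman = list(), rabi = list()) {
  rabi_crop <- unname(croppsi_systems[system_label])
  rows <- list(
    if (rabi_crop == "fallow") {
      make_record(household_id, stratum, system_label, "rabi", "fallow",
                  rice_price_household)
    } else {
      do.call(make_record, c(list(household_id, stratum, system_label,
                                  "rabi", rabi_crop, rice_price_household),
                             rabi))
    },
    make_record(household_id, stratum, system_label, "kharif1", "fallow",
                rice_price_household),
    do.call(make_record, c(list(household_id, stratum, system_label,
                                "kharif2", "aman_rice",
                                rice_price_household), aman))
  )
  dplyr::bind_rows(rows)
}

# The derived toy household used by the arithmetic oracle tests: aman
# grain 2.4 t at the household rice price with straw 2.0 t at a tenth of
# the grain price, plus mungbean 0.9 t at three times the rice price.
toy_mfa_obs <- function(p_r = 17000) {
  make_obs(
    system_label = "MFA", rice_price_household = p_r,
    aman = list(grain_yield = 2.4, crop_price = p_r,
                straw_yield = 2.0, straw_price = 0.1 * p_r),
    rabi = list(grain_yield = 0.9, crop_price = 3 * p_r)
  )
}

# A small but complete two-household survey covering FFA + MFA.
toy_survey <- function() {
  dplyr::bind_rows(
    make_obs("H1", "FFA", aman = list(grain_yield = 2.0, crop_price = 17000,
                                      n_rate = 30, labor_total = 300,
                                      labor_hired = 20, cost_inputs = 8000,
                                      cost_labor = 10000)),
    make_obs("H1", "MFA",
             aman = list(grain_yield = 2.0, crop_price = 17000, n_rate = 30,
                         labor_total = 300, labor_hired = 20,
                         cost_inputs = 8000, cost_labor = 10000),
             rabi = list(grain_yield = 1.0, crop_price = 40000, n_rate = 15,
                         labor_total = 150, labor_hired = 10,
                         cost_inputs = 4000, cost_labor = 5000)),
    make_obs("H2", "FFA", stratum = "outside_polder",
             aman = list(grain_yield = 1.8, crop_price = 16000, n_rate = 28,
                         labor_total = 280, labor_hired = 15,
                         cost_inputs = 7000, cost_labor = 9000),
             rice_price_household = 16000)
  )
}

# A fast generator configuration: both strata shrunk to n households.
small_config <- function(n = 60) {
  cfg <- default_config()
  for (st in names(cfg$strata)) cfg$strata[[st]]$n_households <- as.integer(n)
  cfg
}
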