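# Default energy and greenhouse-gas conversion coefficients.
#
# Every value here is user-overridable; all downstream results are
# conditional on this table. Energy factors are embedded (production +
# delivery) energy for inputs and gross energy content for produce.
# Sources given per entry are the literature standards the defaults
# were taken from.

energy_per_input:        # MJ per kg nutrient, kg a.i., or L
  "n": 60.6              # kg N; Shahan et al. 2008 / standard LCA value
  p2o5: 11.1             # kg P2O5; Shahan et al. 2008
  k2o: 6.7               # kg K2O; Shahan et al. 2008
  pesticide: 120.0       # kg a.i.; Pimentel 1980 (mean across classes)
  fuel: 47.8             # L diesel; lower heating value + upstream

energy_labor: 1.96       # MJ per person-hour of human labor

energy_rice_grain: 14.7  # MJ per kg rice grain (applies to aman and boro)

energy_grain_by_crop:    # MJ per kg produce, non-rice crops
  mungbean: 12.8         # grain at field moisture
  lathyrus: 12.4         # grain at field moisture
  groundnut: 12.5        # fresh in-shell pods (moist basis)
  chili: 5.0             # partially dried marketable fruit

ghg_per_input:           # kg CO2e per kg nutrient, kg a.i., or L
  "n": 4.8               # production + transport of fertilizer N
  p2o5: 0.73
  k2o: 0.55
  pesticide: 19.4        # mean production emissions, kg CO2e per kg a.i.
  fuel: 3.15             # diesel: combustion 2.67 + upstream production

n2o_factors:             # IPCC (2006, Tier 1) fertilizer N2O pathway
  ef1: 0.01              # direct: kg N2O-N per kg N applied
  ef4: 0.010             # indirect, atmospheric deposition of volatilized N
  ef5: 0.0075            # indirect, leaching/runoff
  frac_gasf: 0.10        # fraction of N volatilized as NH3 + NOx
  frac_leach: 0.30       # fraction of N lost to leaching/runoff
  gwp_n2o: 265           # 100-yr GWP of N2O (AR5, no feedbacks)

usd_per_bdt: 0.01284191  # 1 USD = 77.87 BDT (study-year exchange rate)
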