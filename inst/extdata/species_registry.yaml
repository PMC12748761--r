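# Default parameter registry for the cassava tri-trophic system.
# Registry version 1. All stage durations (del) are degree-days on the
# species' own physiological time scale; k is the number of substages of
# the distributed-delay cascade. Demands are resource units per capita per
# day (grams dry matter for herbivores on the plant, host/prey individuals
# for parasitoids and predators). These defaults are documented
# assumptions: the published model's per-species fits are not reproduced
# here, and values were chosen once to yield the qualitative biology of
# the system (A. lopezi dominant over A. diversicornis on mealybug;
# T. aripo, with its plant-based alternative food, dominant over
# A. manihoti on green mite; rain-driven fungal epizootics).
version: 1
sim:
  enemy_lag_days: 60   # natural enemies colonise a planting this many days after the pest
plant:
  dev: {T0: 14.86, Topt: 27.0, Tmax: 40.0, q: 2.0}
  rue: 2.0              # g CH2O per MJ intercepted
  kc: 0.8               # canopy light extinction coefficient
  sla: 0.010            # m2 leaf area per g leaf dry matter
  ground_area: 1.0      # m2 per plant (1 plant per m2)
  lai_max: 4.0
  q10: 2.0
  resp_ref: 0.004       # g g-1 d-1 maintenance respiration at 25 C (leaf+stem)
  resp_tref: 25.0
  wastage: 0.15         # fixed wastage fraction of assimilate
  temp_scalar: {lower: 14.86, opt: 27.0, upper: 40.0}
  leaf_stage: {k: 10, del: 900.0}   # leaf cohort residence, plant dd
  leaf_demand_rate: 1.2             # g leaf growth demand per plant dd
  stem_frac: 0.6                    # stem demand as fraction of leaf demand
  veg_end_dd: 1800.0                # plant age after which demand tapers
  veg_taper: 0.25                   # demand multiplier after veg_end_dd
  labile_cap: 30.0                  # g labile reserve buffer
  cutting_stem: 50.0                # g stem at planting
  cutting_leaf: 10.0                 # g sprouting leaf at planting
  cutting_labile: 25.0              # g labile reserve at planting
  cutting_root: 0.0
  cycle_days: 330
  water_window: 30                  # days of trailing rain for the bucket
  water_demand: 2.5                 # mm per day demand of the bucket
  tip_resource: 40.0                # shoot-tip alternative food units per day
species:
  cm:
    guild: herbivore
    label: cassava mealybug
    dev: {T0: 14.0, Topt: 28.0, Tmax: 35.0, q: 2.0}
    stages:
      immature: {k: 25, del: 150.0}
      adult: {k: 10, del: 250.0}
    fr: {demand: 0.001, alpha: 0.6}
    repro: {first: 20.0, peak: 10.0, shape: 80.0}
    sex_ratio: 1.0                 # thelytokous
    temp_scalar: {lower: 15.0, opt: 28.0, upper: 35.0}
    mort: {mu_min: 0.02, opt: 27.0, c_cold: 0.0008, c_heat: 0.004}
    starv_mort: 0.3
    dispersal: 0.1
    init: {immature: 10.0, adult: 0.0}
  al:
    guild: parasitoid
    label: Anagyrus lopezi
    host: cm
    dev: {T0: 12.0, Topt: 27.0, Tmax: 36.0, q: 2.0}
    stages:
      immature: {k: 25, del: 180.0}
      adult: {k: 10, del: 150.0}
    fr: {demand: 15.0, alpha: 0.85}
    preference: {immature: 0.7, adult: 0.3}
    sex_ratio: 0.5
    temp_scalar: {lower: 13.0, opt: 27.0, upper: 36.0}
    mort: {mu_min: 0.06, opt: 26.0, c_cold: 0.001, c_heat: 0.004}
    starv_mort: 0.25
    dispersal: 0.3
    init: {immature: 0.0, adult: 0.5}
  ad:
    guild: parasitoid
    label: Anagyrus diversicornis
    host: cm
    dev: {T0: 12.0, Topt: 27.0, Tmax: 36.0, q: 2.0}
    stages:
      immature: {k: 25, del: 180.0}
      adult: {k: 10, del: 150.0}
    fr: {demand: 12.0, alpha: 0.08}
    preference: {immature: 1.0, adult: 0.0}
    sex_ratio: 0.5
    temp_scalar: {lower: 13.0, opt: 27.0, upper: 36.0}
    mort: {mu_min: 0.06, opt: 26.0, c_cold: 0.001, c_heat: 0.004}
    starv_mort: 0.25
    dispersal: 0.3
    init: {immature: 0.0, adult: 0.5}
  p_cm:
    guild: pathogen
    label: Neozygites fumosa
    host: cm
    transmissivity: 0.12           # per day at scalar = 1
    rain: {half_rain: 12.0, rh_lo: 50.0, rh_hi: 90.0, window: 7}
    incubation: {k: 10, del: 60.0} # on the host's physiological time
  cgm:
    guild: herbivore
    label: cassava green mite
    dev: {T0: 10.0, Topt: 31.0, Tmax: 38.0, q: 2.0}
    stages:
      immature: {k: 25, del: 120.0}
      adult: {k: 10, del: 150.0}
    fr: {demand: 0.0002, alpha: 0.1}
    damage_mult: 1.5               # g leaf destroyed per g ingested
    repro: {first: 10.0, peak: 4.0, shape: 60.0}
    sex_ratio: 0.7
    temp_scalar: {lower: 12.0, opt: 31.0, upper: 38.0}
    mort: {mu_min: 0.03, opt: 30.0, c_cold: 0.0008, c_heat: 0.005}
    starv_mort: 0.3
    dispersal: 0.25
    init: {immature: 10.0, adult: 0.0}
  ta:
    guild: predator
    label: Typhlodromalus aripo
    prey: cgm
    dev: {T0: 11.0, Topt: 28.0, Tmax: 38.0, q: 2.0}
    stages:
      immature: {k: 25, del: 100.0}
      adult: {k: 10, del: 200.0}
    fr: {demand: 5.0, alpha: 0.7}
    preference: {immature: 0.8, adult: 0.2}
    alt_food: true                 # shoot-tip pollen/exudate resource
    repro: {first: 15.0, peak: 2.0, shape: 80.0}
    sex_ratio: 0.7
    temp_scalar: {lower: 13.0, opt: 28.0, upper: 38.0}
    mort: {mu_min: 0.05, opt: 27.0, c_cold: 0.001, c_heat: 0.004}
    starv_mort: 0.25
    dispersal: 0.25
    init: {immature: 0.0, adult: 0.5}
  am:
    guild: predator
    label: Amblydromalus manihoti
    prey: cgm
    dev: {T0: 11.0, Topt: 29.0, Tmax: 38.0, q: 2.0}
    stages:
      immature: {k: 25, del: 90.0}
      adult: {k: 10, del: 180.0}
    fr: {demand: 8.0, alpha: 0.75}
    preference: {immature: 0.8, adult: 0.2}
    alt_food: false
    repro: {first: 12.0, peak: 3.0, shape: 70.0}
    sex_ratio: 0.7
    temp_scalar: {lower: 13.0, opt: 29.0, upper: 38.0}
    mort: {mu_min: 0.05, opt: 28.0, c_cold: 0.001, c_heat: 0.004}
    starv_mort: 0.4
    dispersal: 0.25
    init: {immature: 0.0, adult: 0.5}
  p_cgm:
    guild: pathogen
    label: Neozygites tanajoae
    host: cgm
    transmissivity: 0.08
    rain: {half_rain: 15.0, rh_lo: 50.0, rh_hi: 90.0, window: 7}
    incubation: {k: 10, del: 50.0}
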