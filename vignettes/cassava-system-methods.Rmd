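---
title: "Methods: the cassava tri-trophic system model and its bioeconomic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cassava tri-trophic system model and its bioeconomic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cassavabc)
```

# Scope and design

`cassavabc` is a desk-scale reconstruction of a weather-driven
physiologically based demographic model (PBDM) of the African cassava
system — plant, cassava mealybug (CM), cassava green mite (CGM), their
introduced parasitoids and predators, and endemic fungal pathogens —
together with the factorial scenario design and marginal regression
analysis used to parse each natural enemy's contribution to pest
suppression and yield recovery.  Two deliberately different standards of
fidelity coexist:

* the **bioeconomic layer** reproduces the published regression
  arithmetic *exactly*, from coefficients transcribed at full printed
  precision (`load_printed_equation()`), and
* the **simulation layer** is verified against conservation laws,
  closed-form oracles and the system's qualitative biology, *not*
  against the Africa-wide numbers, which depended on a continental
  weather archive and a 10,172-cell grid that are out of scope here.

# The population dynamics engine

Each life stage is a time-invariant distributed maturation time stage
with attrition: `k` substages in cascade, total mean duration `del`
degree-days, giving Erlang transit times with mean `del` and coefficient
of variation `1/sqrt(k)`.  The daily update moves the flow fraction
`f = k d_phys / del` between substages; if `f > 1` the day is split into
equal sub-steps until each satisfies the bound, so the explicit update
stays non-negative without changing the model.  Attrition is applied
*after* the flow within each sub-step as `exp(-mu dt)`; the order is
fixed for reproducibility, and the exponential form keeps survival
nearly step-size independent.  In the fine-step limit the fraction
completing a stage under attrition approaches the closed form
`(1 + mu del / k)^(-k)` (`stage_survival()`), which the tests verify to
1% along with exact mass balance of the cumulative inflow/outflow
counters.

The published model's per-stage `k` and `del` are in its supplemental
material, which is not reproduced here; the registry defaults use
`k = 25` for arthropod stages (moderate developmental spread), `k = 10`
for adult stages and plant leaf cohorts, with durations chosen for each
species' typical generation time.  The time-varying form of the delay is
not implemented: stage durations vary only through physiological time.

# Biodemographic functions

Temperature-dependent development uses a beta-family unimodal rate,
`r(T) = rmax u^q v^(q (Tmax - Topt)/(Topt - T0))` with
`u = (T - T0)/(Topt - T0)` and `v = (Tmax - T)/(Tmax - Topt)`: zero at
and beyond both thresholds, maximal exactly at `Topt`, with the slow
rise and sharp high-temperature collapse characteristic of ectotherm
development.  This family was chosen over a Brière-type curve because the
optimum is an explicit, independently settable parameter rather than a
consequence of the two thresholds — the contract the parameter objects
validate (`T0 < Topt < Tmax`).  The cassava threshold is 14.86 °C (the
source prints both 14.86 and 14.85 °C in different places; the body-text
value is used).  Daily degree-days integrate the rate over a 24-point
sine interpolation between `tmin` and `tmax`, rescaled so a full day at
the optimum accrues `Topt - T0` degree-days; a constant day reproduces
the pointwise rate exactly, and sinusoidal days agree with a fine-grid
quadrature oracle to four significant digits.

All consumption passes through the demand-driven functional response
`S = D (1 - exp(-alpha R / D))`, which guarantees `0 <= S < D` and
`S <= alpha R`; the resulting supply/demand ratio gates fecundity
(multiplicatively, together with the unimodal temperature scalar and the
age-specific reproduction profile), starvation mortality
(`starv_mort * (1 - S/D)` per day), and emigration
(`dispersal * (1 - S/D)` of mobile stages, pooled and redistributed
uniformly across the lattice, conserving totals exactly).  Fungal
infection multiplies a base transmissivity by a rain/humidity scalar: a
Michaelis term in trailing 7-day rainfall (half-saturation per species)
times a humidity ramp, capturing the wet-season epizootics that drive
both pathogens.

# The plant

Cassava is modelled as a metabolic pool: Beer's-law light interception
(`1 - exp(-kc LAI)`) times a radiation-use efficiency and the
temperature and water scalars yields daily assimilate, which is
allocated in priority order — fixed wastage fraction, Q10 maintenance
respiration (drawing down a small labile reserve when short, flagging
stress when both fail), vegetative growth rationed by the plant-level
supply/demand ratio, labile-buffer refill, residual to the root/tuber
pool.  The daily ledger balances to floating-point precision and is
asserted to 1e-9 relative error in the tests.  Leaf cohorts age through
the distributed-delay engine (senescence is the stage outflow); mealybug
feeding drains assimilate before allocation; green-mite feeding destroys
leaf mass (and hence area) after allocation, at `damage_mult` grams per
gram ingested.

The water scalar is a simple bucket — trailing 30-day rainfall over a
2.5 mm/day demand, capped at 1 — standing in for a soil model the source
does not provide; it suffices to reproduce the rainfall isohyet
structure of the cassava belt (humid cells above the 1500 g/plant belt
threshold, semi-arid and arid cells below it).

Crop cycles are fixed at 330 days from a cutting (50 g stem, 25 g labile
reserve, 10 g sprouting leaf) to harvest, with immediate replanting; the
source runs continuous multi-year simulations without stating a cropping
calendar, and a fixed cycle makes annual yields well-defined.  Annual
yield is the lattice mean of the harvests falling in that calendar year.

# The trophic web and its calibration targets

Parasitoid attacks convert hosts into the parasitoid's immature stage
(no superparasitism, no host feeding); predator kills are the prey share
of the functional-response supply; both are distributed over host/prey
stages by preference weights and jointly capped at availability.
*T. aripo* has a plant shoot-tip alternative food that keeps its supply
positive at zero prey; *A. manihoti* has higher demand and fecundity but
no fallback.  Intraguild interaction between the two predators is purely
exploitative competition through the shared prey pool.

Pests colonise each planting at once; natural enemies follow 60 days
later (`sim: enemy_lag_days`), reflecting the colonisation sequence of a
young planting.  Without the lag, nominal enemy inocula annihilate the
nominal pest inocula before either establishes, a regime the source's
dynamics plainly do not inhabit.

Because the per-species parameter fits are unavailable, the registry
defaults are documented assumptions calibrated *once* to the system's
qualitative orderings, which the tests then assert on seeded humid-regime
runs:

* cumulative CM: `{Al, P} < {Ad, P} < {P} < {none}` — *A. lopezi*
  controls, *A. diversicornis* only suppresses partially (its search
  rate is an order of magnitude lower and it attacks immatures only);
* with both parasitoids present, *A. diversicornis* is displaced
  (cumulative Ad-parasitised far below Al-parasitised), while reaching
  high densities when *A. lopezi* is absent;
* cumulative CGM: `{Ta} < {Am}` — *T. aripo* persists between outbreaks
  on tip food and prevents them; *A. manihoti* booms during an outbreak
  (its cumulative density exceeds *T. aripo*'s) but starves out and
  fails;
* yields: pest-free ≥ enemy-controlled ≥ uncontrolled.

# Synthetic weather

The generator replaces the continental weather archive with regimes that
have the statistical structure of tropical cassava-zone climates: a
seasonal temperature sinusoid with fixed diurnal range and Gaussian
noise; two-state Markov wet/dry occurrence gated by wet-season windows;
gamma wet-day amounts whose scale is derived from the target annual
total and the chain's stationary wet-day frequency; humidity raised and
solar lowered on wet days.  Years are 365 days with no leap handling
(nothing in the model is leap-sensitive).  Four presets span the
rainfall gradient (1200, 900, 550, 300 mm) that brackets the ~750–800 mm
isohyets bounding cassava production.  The generator does not emulate
spatial correlation between cells, multi-day storm persistence beyond
the first-order chain, or interannual drivers such as ENSO — so passing
tests show the model responds correctly to realistic *within-year*
weather structure, not that it reproduces any particular historical
series.

# Scenario design and the regression layer

`factorial_table()` crosses the four toggles of a subsystem
(CM × Al × Ad × P, or CGM × Ta × Am × P) with regimes and seeds: 16
dummy combinations per cell, of which the nine with no orphan enemies
are dynamically distinct (an enemy without its pest has no effect; such
rows are structural zeros carrying their design dummies, simulated once
through their canonical equivalent).  The first simulated year is
excluded as equilibration.  `belt_filter()` judges belt membership on
the pest-free baseline yield, so a cell's suitability does not depend on
the pest treatment applied to it.

`fit_dummy_regression()` is OLS with one-term-at-a-time backward
elimination by largest p-value above `alpha`; hierarchy is deliberately
*not* enforced, because the published CGM yield model retains a
three-way interaction without its two-way parents.  Two companion-mean
conventions coexist in the published marginal arithmetic, and
`marginal_effect()` exposes both: `"product"` (default) multiplies the
printed main-effect means, which recovers the great majority of the
printed values; `"term"` substitutes the printed interaction-column mean
where the companion product is itself a model term, which is the only
way to recover the pathogen marginal in the five-term CGM density model.
`reproduce_marginals()` evaluates every printed marginal under both
conventions with a tolerance that propagates the printing precision
(half a last-digit unit plus the effect of the means being rounded to
three decimals) and flags what cannot be recovered — exactly one value,
the *A. diversicornis* effect in the full mealybug model, is flagged;
its printed value does not follow from the printed coefficients under
either convention.  Predictions at means use each term's own printed
column mean throughout.

# Numerical choices and problem sizes

Sub-stepping bounds every explicit update; all removals (parasitism,
predation, infection, dispersal) are proportional over substages and
jointly capped at availability, so abundances cannot go negative; ties
in backward elimination resolve to the first-listed term (`which.max`).
The test suite runs the qualitative-ordering scenarios on 3-plant,
3-year humid lattices and the regression-recovery study on a full 2^3
design with 200 replicates per cell plus a 100-replicate coverage check
— sizes chosen so the whole suite completes in well under a minute while
leaving every assertion comfortably away from its threshold.

# Known limitations

Plants within a lattice are identical (shared weather, same planting
day), so dispersal only redistributes during transients; nutrient
limitation, variety differences, root quality and intercropping are
omitted; the native coccinellid predators of CM and *N. idaeus* are
excluded as in the source analysis; pathogen dynamics are
phenomenological (no conidial pool or strain structure); and the
printed R², F, df and t-values of the fixture equations are metadata
from the original Africa-wide fit — they are reported, not refit, since
the underlying weather and grid are not reproduced here.
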