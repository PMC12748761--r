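#' Metabolic-pool cassava canopy model
#'
#' Daily photosynthate acquisition and priority allocation to
#' age-structured leaf cohorts, stem, labile reserves, and the root/tuber
#' pool.  The allocation priority is: fixed wastage fraction, then
#' temperature-dependent (Q10) maintenance respiration (drawing down the
#' labile reserve when assimilate is short), then vegetative growth
#' rationed by the plant-level supply/demand ratio, then refill of the
#' labile buffer, with the residual banked in the root/tuber reserve.
#' Every day balances an exact dry-matter ledger.
#'
#' @name cassava_plant
NULL

#' Initialise a cassava plant from a cutting
#'
#' @param p plant parameter block of a registry (see [load_registry()]).
#' @return a `plant_state`: leaf cohort stage (seeded with the cutting's
#'   sprouting leaves), stem / root / labile masses (g dry matter), and
#'   plant physiological age (dd above 14.86 C).
#' @export
new_plant <- function(p) {
  structure(list(
    leaf = stage_state(p$leaf_stage, p$cutting_leaf),
    stem = p$cutting_stem,
    root = p$cutting_root,
    labile = p$cutting_labile,
    age = 0,
    stressed = FALSE
  ), class = "plant_state")
}

#' Leaf area of a plant
#'
#' @param state a `plant_state`.
#' @param p plant parameter block.
#' @return green leaf area, m2 (leaf mass times specific leaf area).
#' @export
leaf_area <- function(state, p) stage_total(state$leaf) * p$sla

#' Daily gross photosynthesis
#'
#' Beer's-law light interception over the canopy times a radiation-use
#' efficiency, corrected by the temperature scalar and the water scalar.
#'
#' @param solar solar radiation, MJ m-2 d-1.
#' @param area leaf area, m2.
#' @param temp mean temperature, degrees C.
#' @param water water scalar in `[0, 1]` from the rainfall bucket.
#' @param p plant parameter block.
#' @return g CH2O assimilated per plant per day.
#' @export
photosynthesis <- function(solar, area, temp, water, p) {
  if (solar < 0 || area < 0) stop("photosynthesis: negative input")
  if (water < 0 || water > 1) stop("photosynthesis: water scalar in [0,1]")
  lai <- area / p$ground_area
  p$rue * solar * p$ground_area * (1 - exp(-p$kc * lai)) *
    temp_scalar(temp, p$temp_scalar) * water
}

#' Priority allocation of the day's assimilate
#'
#' @param assim g CH2O available after herbivore off-take (>= 0).
#' @param demands named numeric vector `c(leaf = , stem = )` of vegetative
#'   growth demands, g.
#' @param temp mean temperature, degrees C.
#' @param state a `plant_state`.
#' @param p plant parameter block.
#' @return list with `state` (masses updated; leaf growth returned as
#'   `leaf_inflow` for the cohort engine, not yet applied) and `ledger`,
#'   an exact daily balance: `assimilate = wastage + respiration +
#'   growth_leaf + growth_stem + to_reserves + to_root` where
#'   `respiration` includes any reserve-funded part and `to_reserves` is
#'   the net labile change (negative when drawn down).
#' @export
allocate <- function(assim, demands, temp, state, p) {
  if (assim < 0) stop("allocate: negative assimilate")
  if (any(demands < 0)) stop("allocate: negative demand")
  wastage <- p$wastage * assim
  avail <- assim - wastage

  resp_need <- p$resp_ref * p$q10^((temp - p$resp_tref) / 10) *
    (stage_total(state$leaf) + state$stem)
  resp_from_assim <- min(avail, resp_need)
  avail <- avail - resp_from_assim
  short <- resp_need - resp_from_assim
  reserve_draw <- min(state$labile, short)
  state$labile <- state$labile - reserve_draw
  state$stressed <- short > reserve_draw + 1e-12
  respiration <- resp_from_assim + reserve_draw

  total_demand <- sum(demands)
  sd_ratio <- if (total_demand > 0) min(1, avail / total_demand) else 1
  growth <- demands * sd_ratio
  avail <- avail - sum(growth)

  to_labile <- min(avail, max(0, p$labile_cap - state$labile))
  state$labile <- state$labile + to_labile
  to_root <- avail - to_labile
  state$root <- state$root + to_root
  state$stem <- state$stem + unname(growth["stem"])

  ledger <- list(assimilate = assim, wastage = wastage,
                 respiration = respiration,
                 growth_leaf = unname(growth["leaf"]),
                 growth_stem = unname(growth["stem"]),
                 to_reserves = to_labile - reserve_draw,
                 to_root = to_root, sd_ratio = sd_ratio)
  list(state = state, ledger = ledger, leaf_inflow = unname(growth["leaf"]))
}

plant_demands <- function(state, dd, p) {
  lai <- leaf_area(state, p) / p$ground_area
  taper <- if (state$age > p$veg_end_dd) p$veg_taper else 1
  leaf_d <- max(0, p$leaf_demand_rate * dd * (1 - lai / p$lai_max)) * taper
  c(leaf = leaf_d, stem = p$stem_frac * leaf_d)
}

#' Resources a plant offers on a given day
#'
#' Computed before herbivore feeding: prospective gross assimilate (the
#' resource mealybugs tap), green leaf mass (the resource green mites
#' consume), and the shoot-tip alternative-food supply used by
#' T. aripo.
#'
#' @param state a `plant_state`.
#' @param wx one-row weather record (`tmax`, `tmin`, `solar`, `rh`).
#' @param water water scalar in `[0, 1]`.
#' @param p plant parameter block.
#' @export
plant_resources <- function(state, wx, water, p) {
  temp <- (wx$tmax + wx$tmin) / 2
  area <- leaf_area(state, p)
  gross <- photosynthesis(wx$solar, area, temp, water, p)
  list(assim = gross, leaf_mass = stage_total(state$leaf),
       tips = if (area > 0) p$tip_resource else 0)
}

#' Advance a plant by one day
#'
#' Applies mealybug off-take (sap drain, removed from assimilate before
#' allocation), allocates the remainder, grows and senesces the leaf
#' cohort through the distributed-delay engine, then removes green-mite
#' leaf damage (leaf mass and area) after allocation.
#'
#' @param state a `plant_state`.
#' @param wx one-row weather record.
#' @param water water scalar in `[0, 1]`.
#' @param cm_drain realised mealybug supply, g assimilate (>= 0).
#' @param cgm_damage leaf mass destroyed by green mite feeding, g (>= 0).
#' @param p plant parameter block.
#' @return list `state`, `ledger` (with `offtake` and `leaf_damage`
#'   added), `dd` (plant physiological time of the day).
#' @export
grow_plant_day <- function(state, wx, water, cm_drain = 0, cgm_damage = 0,
                           p) {
  if (cm_drain < 0 || cgm_damage < 0) stop("grow_plant_day: negative drain")
  temp <- (wx$tmax + wx$tmin) / 2
  dd <- daily_physio_time(wx$tmax, wx$tmin, p$dev)
  res <- plant_resources(state, wx, water, p)
  offtake <- min(cm_drain, res$assim)
  assim <- res$assim - offtake

  demands <- plant_demands(state, dd, p)
  al <- allocate(assim, demands, temp, state, p)
  state <- al$state

  stepped <- step_stage(state$leaf, p$leaf_stage, al$leaf_inflow, dd, mu = 0)
  state$leaf <- stepped$state

  damage <- min(cgm_damage, stage_total(state$leaf))
  if (damage > 0) {
    tot <- stage_total(state$leaf)
    state$leaf$x <- state$leaf$x * (1 - damage / tot)
    state$leaf$cum_out <- state$leaf$cum_out + damage
  }
  state$age <- state$age + dd

  ledger <- al$ledger
  ledger$assimilate <- res$assim
  ledger$offtake <- offtake
  ledger$leaf_damage <- damage
  ledger$senescence <- stepped$outflow
  list(state = state, ledger = ledger, dd = dd)
}

#' Current root/tuber yield of a plant
#'
#' @param state a `plant_state`.
#' @return g root dry matter per plant.
#' @export
root_yield <- function(state) state$root
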