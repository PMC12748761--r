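#' Trophic web: herbivory, parasitism, predation, infection, dispersal
#'
#' Couples the mealybug (CM) and green mite (CGM) to the plant, the
#' parasitoids A. lopezi (al) and A. diversicornis (ad) to CM, the
#' predatory mites T. aripo (ta, with a plant shoot-tip alternative food)
#' and A. manihoti (am) to CGM, and the rain-driven fungal pathogens to
#' both pests.  All consumption passes through the demand-driven
#' [acquisition()] functional response, so every consumer carries a daily
#' supply/demand ratio that gates its fecundity, survival and emigration.
#'
#' @name trophic_web
NULL

#' Herbivore feeding on a plant resource
#'
#' @param n_active number of feeding individuals (>= 0).
#' @param demand_pc per-capita demand, resource units per day.
#' @param alpha search rate in (0, 1].
#' @param resource available plant resource (assimilate for CM, leaf mass
#'   for CGM).
#' @return list `supply` (= plant drain), `demand`, `sd` (supply/demand,
#'   1 when there is no demand).
#' @export
herbivore_feeding <- function(n_active, demand_pc, alpha, resource) {
  if (n_active < 0 || resource < 0) stop("herbivore_feeding: negative input")
  D <- n_active * demand_pc
  if (D <= 0) return(list(supply = 0, demand = 0, sd = 1))
  S <- acquisition(D, resource, alpha)
  list(supply = S, demand = D, sd = S / D)
}

#' Parasitoid attack on host stages
#'
#' Attacks are drawn from the functional response against the
#' preference-weighted host pool and distributed over host stages in
#' proportion to weighted availability; with weights summing to 1 no
#' stage can be over-attacked.
#'
#' @param hosts named vector of available hosts per stage.
#' @param females adult female parasitoids.
#' @param demand_pc eggs per female per day.
#' @param alpha search rate.
#' @param preference named weights over `names(hosts)` (sum to 1).
#' @return list `attacks` (named, by host stage), `total`, `sd`.
#' @export
parasitism <- function(hosts, females, demand_pc, alpha, preference) {
  if (any(hosts < 0) || females < 0) stop("parasitism: negative input")
  w <- preference[names(hosts)]
  w[is.na(w)] <- 0
  R <- sum(w * hosts)
  D <- females * demand_pc
  if (D <= 0 || R <= 0)
    return(list(attacks = hosts * 0, total = 0, sd = if (D <= 0) 1 else 0))
  S <- acquisition(D, R, alpha)
  attacks <- S * (w * hosts) / R
  list(attacks = attacks, total = S, sd = S / D)
}

#' Predation on prey stages, with optional alternative food
#'
#' The predator's resource is the preference-weighted prey pool plus, for
#' T. aripo, a plant shoot-tip alternative food that keeps its supply
#' positive at zero prey.  Prey kills are the prey-derived share of the
#' realised supply.
#'
#' @param prey named vector of available prey per stage.
#' @param females adult female predators.
#' @param demand_pc prey (or prey-equivalents) per female per day.
#' @param alpha search rate.
#' @param preference named weights over `names(prey)`.
#' @param alt_food alternative-food resource, prey-equivalents per day.
#' @return list `kills` (named, by prey stage), `supply`, `sd`.
#' @export
predation <- function(prey, females, demand_pc, alpha, preference,
                      alt_food = 0) {
  if (any(prey < 0) || females < 0 || alt_food < 0)
    stop("predation: negative input")
  w <- preference[names(prey)]
  w[is.na(w)] <- 0
  preyR <- sum(w * prey)
  R <- preyR + alt_food
  D <- females * demand_pc
  if (D <= 0 || R <= 0)
    return(list(kills = prey * 0, supply = 0, sd = if (D <= 0) 1 else 0))
  S <- acquisition(D, R, alpha)
  prey_share <- preyR / R
  kills <- if (preyR > 0) S * prey_share * (w * prey) / preyR else prey * 0
  list(kills = kills, supply = S, sd = S / D)
}

#' Rain-driven fungal infection of host stages
#'
#' @param susceptible named vector of susceptible hosts per stage.
#' @param transmissivity base daily infection rate at scalar 1.
#' @param scalar rain/humidity multiplier in `[0, 1]` from
#'   [pathogen_scalar()].
#' @return named vector of newly infected hosts (never exceeding
#'   availability).
#' @export
infection <- function(susceptible, transmissivity, scalar) {
  if (any(susceptible < 0)) stop("infection: negative input")
  if (scalar < 0 || scalar > 1) stop("infection: scalar must be in [0, 1]")
  pmin(susceptible, susceptible * transmissivity * scalar)
}

#' Supply/demand-driven dispersal across the plant lattice
#'
#' On each plant the emigrating fraction of a mobile stage is
#' `rate * (1 - sd)`; emigrants from all plants are pooled (substage by
#' substage, preserving age structure) and redistributed uniformly across
#' all plants including the origin.  Totals are conserved exactly.
#'
#' @param stages list with one substage-abundance vector per plant.
#' @param sd_ratio per-plant supply/demand ratios in `[0, 1]`.
#' @param rate maximum emigration fraction at sd = 0.
#' @return list of updated substage vectors.
#' @export
dispersal <- function(stages, sd_ratio, rate) {
  n <- length(stages)
  if (length(sd_ratio) != n) stop("dispersal: one sd ratio per plant")
  if (any(sd_ratio < 0 | sd_ratio > 1))
    stop("dispersal: sd ratios must be in [0, 1]")
  if (rate < 0 || rate > 1) stop("dispersal: rate must be in [0, 1]")
  frac <- rate * (1 - sd_ratio)
  pool <- 0
  for (i in seq_len(n)) {
    emig <- frac[i] * stages[[i]]
    stages[[i]] <- stages[[i]] - emig
    pool <- pool + emig
  }
  share <- pool / n
  for (i in seq_len(n)) stages[[i]] <- stages[[i]] + share
  stages
}

# ---- per-plant community -------------------------------------------------

new_community <- function(reg, enabled) {
  pop <- list()
  for (nm in c("cm", "al", "ad", "cgm", "ta", "am")) {
    if (!enabled[[nm]]) next
    s <- reg$species[[nm]]
    pop[[nm]] <- list(im = stage_state(s$stages$immature, 0),
                      ad = stage_state(s$stages$adult, 0))
  }
  if (enabled[["p_cm"]] && enabled[["cm"]])
    pop$cm$inf <- stage_state(reg$species$p_cm$incubation, 0)
  if (enabled[["p_cgm"]] && enabled[["cgm"]])
    pop$cgm$inf <- stage_state(reg$species$p_cgm$incubation, 0)
  list(plant = new_plant(reg$plant), pop = pop,
       cum = c(cm = 0, cgm = 0, al_par = 0, ad_par = 0, ta = 0, am = 0))
}

inoculate <- function(comm, reg, enabled,
                      group = c("cm", "al", "ad", "cgm", "ta", "am")) {
  for (nm in group) {
    if (!enabled[[nm]]) next
    init <- reg$species[[nm]]$init
    comm$pop[[nm]]$im$x[1L] <- comm$pop[[nm]]$im$x[1L] + init$immature
    comm$pop[[nm]]$im$cum_in <- comm$pop[[nm]]$im$cum_in + init$immature
    comm$pop[[nm]]$ad$x[1L] <- comm$pop[[nm]]$ad$x[1L] + init$adult
    comm$pop[[nm]]$ad$cum_in <- comm$pop[[nm]]$ad$cum_in + init$adult
  }
  comm
}

# remove `n` individuals from a stage_state, proportionally over substages
remove_from_stage <- function(ss, n) {
  tot <- sum(ss$x)
  if (tot <= 0 || n <= 0) return(ss)
  n <- min(n, tot)
  ss$x <- ss$x * (1 - n / tot)
  ss$cum_out <- ss$cum_out + n
  ss
}

adult_ages <- function(cfg) (seq_len(cfg$k) - 0.5) * cfg$del / cfg$k

# total eggs laid by an adult stage given temperature and supply/demand
stage_births <- function(ad_state, cfg, temp, sd, s) {
  if (is.null(s$repro)) return(0)
  ages <- adult_ages(cfg)
  sum(ad_state$x * fecundity(ages, temp, sd, s$repro, s$temp_scalar))
}

# advance one arthropod population by a day: births in, attrition, aging
step_population <- function(pp, s, dd, temp, sd, extra_inflow = 0) {
  mu <- mortality_rate(temp, s$mort) + s$starv_mort * (1 - sd)
  births <- stage_births(pp$ad, s$stages$adult, temp, sd, s) + extra_inflow
  im <- step_stage(pp$im, s$stages$immature, births, dd, mu)
  emerge <- im$outflow * s$sex_ratio
  ad <- step_stage(pp$ad, s$stages$adult, emerge, dd, mu)
  pp$im <- im$state
  pp$ad <- ad$state
  pp
}

#' One day of a single-plant community
#'
#' Order of events: plant resources are offered; herbivores feed (their
#' supply is the plant drain); parasitoids and predators attack; fungal
#' infection removes hosts; the plant grows with the drains applied; then
#' every arthropod population reproduces, suffers temperature and
#' starvation attrition, and ages through its stage cascade.  Dispersal
#' between plants is handled at the lattice level by [dispersal()].
#'
#' @param comm a community as built by the scenario runner.
#' @param wx one-row weather record.
#' @param water water scalar in `[0, 1]`.
#' @param path_rain trailing rainfall (mm) for the pathogen scalar.
#' @param dds named list of the day's physiological time per species (and
#'   `plant`).
#' @param enabled named logical over the eight species toggles.
#' @param reg a registry.
#' @return list `comm` (updated) and `sd` (named supply/demand ratios for
#'   the dispersal step).
#' @export
community_step <- function(comm, wx, water, path_rain, dds, enabled, reg) {
  p <- reg$plant
  temp <- (wx$tmax + wx$tmin) / 2
  res <- plant_resources(comm$plant, wx, water, p)
  sp <- reg$species
  sd <- c(cm = 1, al = 1, ad = 1, cgm = 1, ta = 1, am = 1)

  # herbivore feeding
  cm_drain <- 0
  if (!is.null(comm$pop$cm)) {
    n_cm <- stage_total(comm$pop$cm$im) + stage_total(comm$pop$cm$ad)
    fd <- herbivore_feeding(n_cm, sp$cm$fr$demand, sp$cm$fr$alpha, res$assim)
    cm_drain <- fd$supply
    sd["cm"] <- fd$sd
  }
  cgm_damage <- 0
  if (!is.null(comm$pop$cgm)) {
    n_cgm <- stage_total(comm$pop$cgm$im) + stage_total(comm$pop$cgm$ad)
    fd <- herbivore_feeding(n_cgm, sp$cgm$fr$demand, sp$cgm$fr$alpha,
                            res$leaf_mass)
    cgm_damage <- min(res$leaf_mass, fd$supply * sp$cgm$damage_mult)
    sd["cgm"] <- fd$sd
  }

  # parasitism on CM
  attacks <- list(al = c(immature = 0, adult = 0),
                  ad = c(immature = 0, adult = 0))
  if (!is.null(comm$pop$cm)) {
    hosts <- c(immature = stage_total(comm$pop$cm$im),
               adult = stage_total(comm$pop$cm$ad))
    for (pz in c("al", "ad")) {
      if (is.null(comm$pop[[pz]])) next
      par <- parasitism(hosts, stage_total(comm$pop[[pz]]$ad),
                        sp[[pz]]$fr$demand * temp_scalar(temp,
                                                         sp[[pz]]$temp_scalar),
                        sp[[pz]]$fr$alpha, sp[[pz]]$preference)
      attacks[[pz]] <- par$attacks
      sd[pz] <- par$sd
    }
    # joint cap: both parasitoids never remove more than is available
    for (stg in names(hosts)) {
      tot <- attacks$al[stg] + attacks$ad[stg]
      if (tot > hosts[stg] && tot > 0) {
        sc <- hosts[stg] / tot
        attacks$al[stg] <- attacks$al[stg] * sc
        attacks$ad[stg] <- attacks$ad[stg] * sc
      }
    }
    comm$pop$cm$im <- remove_from_stage(comm$pop$cm$im,
                                        attacks$al["immature"] +
                                          attacks$ad["immature"])
    comm$pop$cm$ad <- remove_from_stage(comm$pop$cm$ad,
                                        attacks$al["adult"] +
                                          attacks$ad["adult"])
    comm$cum["al_par"] <- comm$cum["al_par"] + sum(attacks$al)
    comm$cum["ad_par"] <- comm$cum["ad_par"] + sum(attacks$ad)
  }

  # predation on CGM
  kills <- list(ta = c(immature = 0, adult = 0),
                am = c(immature = 0, adult = 0))
  if (!is.null(comm$pop$cgm)) {
    prey <- c(immature = stage_total(comm$pop$cgm$im),
              adult = stage_total(comm$pop$cgm$ad))
    for (pr in c("ta", "am")) {
      if (is.null(comm$pop[[pr]])) next
      alt <- if (isTRUE(sp[[pr]]$alt_food)) res$tips else 0
      pd <- predation(prey, stage_total(comm$pop[[pr]]$ad),
                      sp[[pr]]$fr$demand, sp[[pr]]$fr$alpha,
                      sp[[pr]]$preference, alt)
      kills[[pr]] <- pd$kills
      sd[pr] <- pd$sd
    }
    for (stg in names(prey)) {
      tot <- kills$ta[stg] + kills$am[stg]
      if (tot > prey[stg] && tot > 0) {
        sc <- prey[stg] / tot
        kills$ta[stg] <- kills$ta[stg] * sc
        kills$am[stg] <- kills$am[stg] * sc
      }
    }
    comm$pop$cgm$im <- remove_from_stage(comm$pop$cgm$im,
                                         kills$ta["immature"] +
                                           kills$am["immature"])
    comm$pop$cgm$ad <- remove_from_stage(comm$pop$cgm$ad,
                                         kills$ta["adult"] +
                                           kills$am["adult"])
  }

  # fungal infection
  for (host in c("cm", "cgm")) {
    pz <- paste0("p_", host)
    if (!enabled[[pz]] || is.null(comm$pop[[host]])) next
    pr <- sp[[pz]]$rain
    scal <- pathogen_scalar(path_rain, wx$rh, pr$half_rain, pr$rh_lo,
                            pr$rh_hi)
    sus <- c(immature = stage_total(comm$pop[[host]]$im),
             adult = stage_total(comm$pop[[host]]$ad))
    ninf <- infection(sus, sp[[pz]]$transmissivity, scal)
    comm$pop[[host]]$im <- remove_from_stage(comm$pop[[host]]$im,
                                             ninf["immature"])
    comm$pop[[host]]$ad <- remove_from_stage(comm$pop[[host]]$ad,
                                             ninf["adult"])
    inf <- step_stage(comm$pop[[host]]$inf, sp[[pz]]$incubation, sum(ninf),
                      dds[[host]], mu = 0)
    comm$pop[[host]]$inf <- inf$state   # outflow = deaths, leaves the system
  }

  # plant growth with the drains applied
  g <- grow_plant_day(comm$plant, wx, water, cm_drain, cgm_damage, p)
  comm$plant <- g$state

  # population updates (reproduction, attrition, aging)
  if (!is.null(comm$pop$cm))
    comm$pop$cm[c("im", "ad")] <-
      step_population(comm$pop$cm[c("im", "ad")], sp$cm, dds$cm, temp,
                      sd["cm"])[c("im", "ad")]
  for (pz in c("al", "ad")) {
    if (is.null(comm$pop[[pz]])) next
    # attacked hosts are the parasitoid's immatures
    comm$pop[[pz]] <- step_population(comm$pop[[pz]], sp[[pz]], dds[[pz]],
                                      temp, sd[pz],
                                      extra_inflow = sum(attacks[[pz]]))
  }
  if (!is.null(comm$pop$cgm))
    comm$pop$cgm[c("im", "ad")] <-
      step_population(comm$pop$cgm[c("im", "ad")], sp$cgm, dds$cgm, temp,
                      sd["cgm"])[c("im", "ad")]
  for (pr in c("ta", "am")) {
    if (is.null(comm$pop[[pr]])) next
    comm$pop[[pr]] <- step_population(comm$pop[[pr]], sp[[pr]], dds[[pr]],
                                      temp, sd[pr])
  }

  # daily cumulative statistics (active stages, end of day)
  if (!is.null(comm$pop$cm))
    comm$cum["cm"] <- comm$cum["cm"] + stage_total(comm$pop$cm$im) +
      stage_total(comm$pop$cm$ad)
  if (!is.null(comm$pop$cgm))
    comm$cum["cgm"] <- comm$cum["cgm"] + stage_total(comm$pop$cgm$im)
  if (!is.null(comm$pop$ta))
    comm$cum["ta"] <- comm$cum["ta"] + stage_total(comm$pop$ta$im) +
      stage_total(comm$pop$ta$ad)
  if (!is.null(comm$pop$am))
    comm$cum["am"] <- comm$cum["am"] + stage_total(comm$pop$am$im) +
      stage_total(comm$pop$am$ad)

  list(comm = comm, sd = sd)
}
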