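#' Factorial scenario experiments
#'
#' Runs the coupled system for one climate cell (a regime-seed pair) over
#' multiple years with any combination of species enabled through Boolean
#' absence/presence toggles, and assembles the annual summary tables the
#' bioeconomic analysis consumes.  The first simulated year is treated as
#' an equilibration period and excluded from the output.
#'
#' @name scenario_runner
NULL

#' Define a scenario
#'
#' @param cm,al,ad,p_cm,cgm,ta,am,p_cgm species presence toggles.
#' @param regime a [climate_regime()] or preset name.
#' @param years simulated years (>= 2; the first is excluded from output).
#' @param plants plants in the lattice, 1 to 100 (default 10).
#' @param seed integer seed for the weather stream.
#' @param cell cell identifier for the output table.
#' @param allow_orphans allow an enemy toggle without its pest (the enemy
#'   then has no effect); default FALSE, which makes such combinations an
#'   error.
#' @return a validated `bc_scenario`.
#' @export
scenario <- function(cm = FALSE, al = FALSE, ad = FALSE, p_cm = FALSE,
                     cgm = FALSE, ta = FALSE, am = FALSE, p_cgm = FALSE,
                     regime = "humid", years = 3, plants = 10, seed = 1,
                     cell = NULL, allow_orphans = FALSE) {
  toggles <- c(cm = cm, al = al, ad = ad, p_cm = p_cm,
               cgm = cgm, ta = ta, am = am, p_cgm = p_cgm)
  if (!is.logical(toggles) || anyNA(toggles))
    stop("scenario: toggles must be TRUE/FALSE")
  if (plants < 1 || plants > 100)
    stop("scenario: plants must be in [1, 100]")
  if (years < 2)
    stop("scenario: years must be >= 2 (the first year is excluded)")
  orphans <- character()
  for (en in c("al", "ad", "p_cm")) if (toggles[en] && !toggles["cm"])
    orphans <- c(orphans, en)
  for (en in c("ta", "am", "p_cgm")) if (toggles[en] && !toggles["cgm"])
    orphans <- c(orphans, en)
  if (length(orphans) && !allow_orphans)
    stop("scenario: enemy toggle(s) without their pest: ",
         paste(orphans, collapse = ", "))
  rg <- resolve_regime(regime)
  if (is.null(cell)) cell <- paste(rg$name, seed, sep = "-")
  structure(list(toggles = toggles, regime = rg, years = as.integer(years),
                 plants = as.integer(plants), seed = as.integer(seed),
                 cell = cell),
            class = "bc_scenario")
}

trailing_sum <- function(x, window) {
  cs <- cumsum(x)
  lag <- c(rep(0, window), cs[seq_len(length(x) - window)])
  cs - lag
}

# core engine: simulate one cell under a set of toggles
simulate_cell <- function(s, reg = default_registry()) {
  enabled <- as.list(s$toggles)
  # an enemy without its pest has no dynamics: drop it for the run
  for (en in c("al", "ad", "p_cm")) if (!enabled$cm) enabled[[en]] <- FALSE
  for (en in c("ta", "am", "p_cgm")) if (!enabled$cgm) enabled[[en]] <- FALSE

  wx <- generate_weather(s$regime, s$years, s$seed)
  ndays <- nrow(wx)
  p <- reg$plant

  water <- pmin(1, trailing_sum(wx$rain, p$water_window) /
                  (p$water_window * p$water_demand))
  path_rain <- trailing_sum(wx$rain, reg$species$p_cm$rain$window)

  dd_tab <- list(plant = daily_physio_time(wx$tmax, wx$tmin, p$dev))
  for (nm in c("cm", "al", "ad", "cgm", "ta", "am"))
    if (enabled[[nm]])
      dd_tab[[nm]] <- daily_physio_time(wx$tmax, wx$tmin,
                                        reg$species[[nm]]$dev)

  # pests colonise a planting first; natural enemies follow after a lag
  pests <- c("cm", "cgm")
  enemies <- c("al", "ad", "ta", "am")
  lag <- reg$sim$enemy_lag_days
  if (is.null(lag)) lag <- 60L
  comms <- replicate(s$plants, inoculate(new_community(reg, enabled), reg,
                                         enabled, pests),
                     simplify = FALSE)
  mobile <- intersect(c("cm", "al", "ad", "cgm", "ta", "am"),
                      names(comms[[1]]$pop))

  harvests <- matrix(NA_real_, nrow = s$years, ncol = s$plants)
  n_harv <- integer(s$years)
  cum_prev <- matrix(0, nrow = s$plants, ncol = 6,
                     dimnames = list(NULL, names(comms[[1]]$cum)))
  annual <- vector("list", s$years)
  cycle_day <- 0L

  for (i in seq_len(ndays)) {
    day <- list(tmax = wx$tmax[i], tmin = wx$tmin[i], rain = wx$rain[i],
                solar = wx$solar[i], rh = wx$rh[i])
    dds <- lapply(dd_tab, `[`, i)
    sd_mat <- matrix(1, nrow = s$plants, ncol = 6,
                     dimnames = list(NULL, c("cm", "al", "ad", "cgm",
                                             "ta", "am")))
    for (j in seq_len(s$plants)) {
      st <- community_step(comms[[j]], day, water[i], path_rain[i], dds,
                           enabled, reg)
      comms[[j]] <- st$comm
      sd_mat[j, ] <- st$sd[colnames(sd_mat)]
    }
    if (s$plants > 1L) {
      for (nm in mobile) {
        stages <- lapply(comms, function(cc) cc$pop[[nm]]$ad$x)
        stages <- dispersal(stages, sd_mat[, nm],
                            reg$species[[nm]]$dispersal)
        for (j in seq_len(s$plants)) comms[[j]]$pop[[nm]]$ad$x <- stages[[j]]
      }
    }
    cycle_day <- cycle_day + 1L
    if (cycle_day >= p$cycle_days) {
      yr <- wx$year[i]
      yields <- vapply(comms, function(cc) root_yield(cc$plant), numeric(1))
      if (n_harv[yr] == 0L) harvests[yr, ] <- yields
      else harvests[yr, ] <- harvests[yr, ] + yields
      n_harv[yr] <- n_harv[yr] + 1L
      for (j in seq_len(s$plants)) {
        comms[[j]]$plant <- new_plant(p)
        comms[[j]] <- inoculate(comms[[j]], reg, enabled, pests)
      }
      cycle_day <- 0L
    }
    if (cycle_day == lag)
      for (j in seq_len(s$plants))
        comms[[j]] <- inoculate(comms[[j]], reg, enabled, enemies)
    if (wx$doy[i] == 365L) {
      yr <- wx$year[i]
      cum_now <- t(vapply(comms, function(cc) cc$cum, numeric(6)))
      annual[[yr]] <- colMeans(cum_now - cum_prev)
      cum_prev <- cum_now
    }
  }

  out <- data.frame(cell = s$cell, year = seq_len(s$years),
                    yield_g = rowMeans(harvests) / pmax(1, n_harv),
                    do.call(rbind, lapply(annual, function(a)
                      as.data.frame(as.list(a)))),
                    stringsAsFactors = FALSE)
  names(out)[4:9] <- c("cum_cm", "cum_cgm", "cum_al_par", "cum_ad_par",
                       "cum_ta", "cum_am")
  out <- out[-1, , drop = FALSE]            # first-year equilibration
  rownames(out) <- NULL
  out
}

toggle_dummies <- function(toggles) {
  c(CM = as.integer(toggles[["cm"]]),
    Al = as.integer(toggles[["al"]]),
    Ad = as.integer(toggles[["ad"]]),
    P = as.integer(toggles[["p_cm"]] || toggles[["p_cgm"]]),
    CGM = as.integer(toggles[["cgm"]]),
    Ta = as.integer(toggles[["ta"]]),
    Am = as.integer(toggles[["am"]]))
}

#' Run one scenario
#'
#' @param s a [scenario()].
#' @param reg a registry, default [default_registry()].
#' @return a data.frame with one row per output year: `cell`, `year`,
#'   `yield_g` (lattice-mean g root dry matter per plant), the annual
#'   cumulative per-plant statistics (`cum_cm`, `cum_cgm`, `cum_al_par`,
#'   `cum_ad_par`, `cum_ta`, `cum_am`), and the 0/1 dummy columns `CM`,
#'   `Al`, `Ad`, `P`, `CGM`, `Ta`, `Am`.
#' @export
run_scenario <- function(s, reg = default_registry()) {
  stopifnot(inherits(s, "bc_scenario"))
  out <- simulate_cell(s, reg)
  dum <- toggle_dummies(as.list(s$toggles))
  for (nm in names(dum)) out[[nm]] <- dum[[nm]]
  out
}

#' Full factorial absence/presence experiment for one subsystem
#'
#' Crosses the four toggles of the chosen subsystem (mealybug set:
#' CM x Al x Ad x P; green-mite set: CGM x Ta x Am x P) with the supplied
#' regimes and seeds: 16 toggle combinations per regime-seed cell.
#' Combinations in which an enemy is present without its pest are
#' structural zeros — the enemy has no effect on the dynamics — so each
#' combination is simulated through its canonical equivalent (orphan
#' enemies dropped), cached and re-used, while the emitted dummy columns
#' keep the design values.
#'
#' @param subsystem `"cm"` or `"cgm"`.
#' @param regimes list/vector of regimes or preset names.
#' @param seeds integer seeds (each regime-seed pair is one cell).
#' @param years,plants passed to [scenario()].
#' @param reg a registry.
#' @return long `data.frame` in the same layout as [run_scenario()].
#' @export
factorial_table <- function(subsystem = c("cm", "cgm"),
                            regimes = "humid", seeds = 1L,
                            years = 3, plants = 10,
                            reg = default_registry()) {
  subsystem <- match.arg(subsystem)
  if (!length(regimes) || !length(seeds))
    stop("factorial_table: regimes and seeds must be non-empty")
  vars <- if (subsystem == "cm") c("cm", "al", "ad", "p_cm")
          else c("cgm", "ta", "am", "p_cgm")
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  names(grid) <- vars
  if (!is.list(regimes)) regimes <- as.list(regimes)

  rows <- list()
  for (rgm in regimes) {
    for (sd in seeds) {
      cache <- list()
      for (g in seq_len(nrow(grid))) {
        tg <- as.list(grid[g, , drop = FALSE])
        args <- c(tg, list(regime = rgm, years = years, plants = plants,
                           seed = sd, allow_orphans = TRUE))
        sc <- do.call(scenario, args)
        canon <- sc$toggles
        for (en in c("al", "ad", "p_cm")) if (!canon["cm"]) canon[en] <- FALSE
        for (en in c("ta", "am", "p_cgm")) if (!canon["cgm"])
          canon[en] <- FALSE
        key <- paste(as.integer(canon), collapse = "")
        if (is.null(cache[[key]])) cache[[key]] <- simulate_cell(sc, reg)
        out <- cache[[key]]
        dum <- toggle_dummies(as.list(sc$toggles))
        for (nm in names(dum)) out[[nm]] <- dum[[nm]]
        rows[[length(rows) + 1L]] <- out
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Restrict a scenario table to the cassava belt
#'
#' Keeps the cells whose pest-free (all toggles zero) mean yield exceeds
#' the threshold; the paper's belt criterion is 1500 g dry matter per
#' plant.
#'
#' @param table a scenario table containing the all-off baseline rows.
#' @param threshold g root dry matter per plant (default 1500).
#' @return the filtered table.
#' @export
belt_filter <- function(table, threshold = 1500) {
  dums <- c("CM", "Al", "Ad", "P", "CGM", "Ta", "Am")
  base <- table[rowSums(table[, dums, drop = FALSE]) == 0, , drop = FALSE]
  cells <- unique(table$cell)
  missing <- setdiff(cells, unique(base$cell))
  if (length(missing))
    stop("belt_filter: no all-off baseline for cell(s): ",
         paste(missing, collapse = ", "))
  mean_y <- tapply(base$yield_g, base$cell, mean)
  keep <- names(mean_y)[mean_y > threshold]
  out <- table[table$cell %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a scenario table as CSV
#'
#' @param table a scenario table.
#' @param path file path.
#' @export
write_scenario_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
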