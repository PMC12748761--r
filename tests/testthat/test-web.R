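reg <- default_registry()

test_that("herbivore feeding drains exactly the functional-response supply", {
  expect_equal(herbivore_feeding(0, 0.001, 0.6, 50)$supply, 0)
  z <- herbivore_feeding(10, 1, 0.3, 0)
  expect_equal(z$supply, 0)
  expect_equal(z$sd, 0)
  # demand 10, resource 100, alpha 0.3 -> 10 (1 - e^-3)
  fd <- herbivore_feeding(10, 1, 0.3, 100)
  expect_equal(fd$supply, 10 * (1 - exp(-3)))
  expect_equal(fd$sd, fd$supply / 10)
})

test_that("parasitism respects availability and saturates at egg demand", {
  hosts <- c(immature = 100, adult = 40)
  pref <- c(immature = 0.7, adult = 0.3)
  expect_equal(parasitism(hosts, 0, 15, 0.8, pref)$total, 0)
  z <- parasitism(c(immature = 0, adult = 0), 5, 15, 0.8, pref)
  expect_equal(z$total, 0)
  expect_equal(z$sd, 0)
  # saturating hosts: attacks approach females x demand
  sat <- parasitism(c(immature = 1e7, adult = 1e7), 3, 15, 0.8, pref)
  expect_equal(sat$total, 45, tolerance = 1e-6)
  r <- parasitism(hosts, 4, 15, 0.8, pref)
  expect_true(all(r$attacks <= hosts))
  expect_equal(sum(r$attacks), r$total)
})

test_that("predator alternative food sustains T. aripo but not A. manihoti", {
  prey0 <- c(immature = 0, adult = 0)
  pref <- c(immature = 0.8, adult = 0.2)
  am <- predation(prey0, 2, 8, 0.75, pref, alt_food = 0)
  expect_equal(am$supply, 0)
  expect_equal(am$sd, 0)
  ta <- predation(prey0, 2, 5, 0.7, pref, alt_food = 40)
  expect_gt(ta$supply, 0)
  expect_gt(ta$sd, 0.5)
  expect_equal(sum(ta$kills), 0)               # nothing to kill
  # with prey present the kill is the prey share of the supply
  both <- predation(c(immature = 30, adult = 10), 2, 5, 0.7, pref, 40)
  expect_lt(sum(both$kills), both$supply)
  expect_true(all(both$kills <= c(30, 10)))
})

test_that("joint consumers never remove more prey than exists", {
  # two predators with huge demand on a small pool, as rationed in the
  # community step
  prey <- c(immature = 5, adult = 1)
  pref <- c(immature = 0.8, adult = 0.2)
  k1 <- predation(prey, 50, 8, 0.75, pref, 0)$kills
  k2 <- predation(prey, 50, 5, 0.7, pref, 20)$kills
  tot <- k1 + k2
  sc <- pmin(1, prey / pmax(tot, 1e-300))
  capped <- k1 * sc + k2 * sc
  expect_true(all(capped <= prey + 1e-12))
})

test_that("infection is gated by the rain scalar and dies through the incubation cohort", {
  sus <- c(immature = 100, adult = 50)
  expect_equal(unname(infection(sus, 0.1, 0)), c(0, 0))
  expect_equal(unname(infection(sus, 0.1, 1)), c(10, 5))
  expect_true(all(infection(sus, 5, 1) <= sus))   # capped at availability
  # a pulse of infections all dies: cohort mass balance
  cfg <- reg$species$p_cm$incubation
  st <- stage_state(cfg, 20)
  dead <- 0
  for (i in 1:500) {
    r <- step_stage(st, cfg, 0, 5, 0)
    st <- r$state
    dead <- dead + r$outflow
  }
  expect_equal(dead, 20, tolerance = 1e-9)
})

test_that("dispersal moves starved populations and conserves totals exactly", {
  stages <- list(rep(10, 5), rep(0, 5), rep(2, 5))
  # all plants satisfied: no movement
  same <- dispersal(stages, c(1, 1, 1), 0.2)
  expect_identical(same, stages)
  # one starved plant at maximum rate: exactly 20% emigrates
  moved <- dispersal(stages, c(0, 1, 1), 0.2)
  expect_equal(sum(moved[[1]]), 50 - 10 + 10 / 3)
  before <- sum(unlist(stages))
  expect_equal(sum(unlist(moved)), before, tolerance = 1e-12)
  # random lattices conserve per-substage totals
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    stg <- replicate(n, runif(6, 0, 20), simplify = FALSE)
    sdr <- runif(n)
    out <- dispersal(stg, sdr, runif(1, 0, 1))
    expect_equal(Reduce(`+`, out), Reduce(`+`, stg), tolerance = 1e-12)
  }
  expect_error(dispersal(stages, c(0.5, 0.5), 0.2), "one sd ratio")
})

test_that("a community day preserves non-negativity and links plant drain to supply", {
  enabled <- list(cm = TRUE, al = TRUE, ad = FALSE, p_cm = TRUE,
                  cgm = FALSE, ta = FALSE, am = FALSE, p_cgm = FALSE)
  comm <- cassavabc:::new_community(reg, enabled)
  comm <- cassavabc:::inoculate(comm, reg, enabled)
  comm$plant$leaf <- stage_state(reg$plant$leaf_stage, 150)
  dds <- list(plant = 10, cm = 11, al = 12)
  day <- list(tmax = 30, tmin = 22, rain = 4, solar = 20, rh = 75)
  for (i in 1:30) {
    st <- community_step(comm, day, 0.9, 25, dds, enabled, reg)
    comm <- st$comm
    for (nm in names(comm$pop))
      for (stg in names(comm$pop[[nm]]))
        expect_true(all(comm$pop[[nm]][[stg]]$x >= 0))
    expect_true(all(st$sd >= 0 & st$sd <= 1))
  }
  expect_gt(stage_total(comm$pop$cm$im) + stage_total(comm$pop$cm$ad), 0)
})
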