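reg <- default_registry()
pp <- reg$plant

test_that("photosynthesis follows Beer's law and shuts off without leaves", {
  expect_equal(photosynthesis(20, 0, 26, 1, pp), 0)
  # LAI = 1 with kc = 0.8: interception factor 1 - exp(-0.8)
  got <- photosynthesis(20, pp$ground_area, 26, 1, pp)
  ts <- temp_scalar(26, pp$temp_scalar)
  expect_equal(got, pp$rue * 20 * pp$ground_area * (1 - exp(-0.8)) * ts)
  # saturating canopy: interception approaches 1
  big <- photosynthesis(20, 1000, 26, 1, pp)
  expect_equal(big, pp$rue * 20 * pp$ground_area * ts, tolerance = 1e-6)
  expect_lt(photosynthesis(20, 2, 26, 0.5, pp),
            photosynthesis(20, 2, 26, 1, pp))
})

test_that("allocation balances the dry-matter ledger exactly", {
  st <- new_plant(pp)
  st$leaf <- stage_state(pp$leaf_stage, 100)
  # plenty of assimilate: demands met in full, surplus banked in the root
  al <- allocate(100, c(leaf = 10, stem = 6), 26, st, pp)
  lg <- al$ledger
  expect_equal(lg$assimilate,
               lg$wastage + lg$respiration + lg$growth_leaf +
                 lg$growth_stem + lg$to_reserves + lg$to_root,
               tolerance = 1e-12)
  expect_equal(lg$sd_ratio, 1)
  expect_equal(lg$growth_leaf, 10)
  expect_gt(lg$to_root, 0)
  expect_error(allocate(10, c(leaf = -1, stem = 0), 26, st, pp),
               "negative demand")
})

test_that("scarce assimilate rations growth proportionally and starvation flags stress", {
  st <- new_plant(pp)
  st$leaf <- stage_state(pp$leaf_stage, 100)
  st$labile <- 0
  # supply covering half the vegetative demand after wastage + respiration
  resp <- pp$resp_ref * pp$q10^((26 - pp$resp_tref) / 10) * (100 + st$stem)
  assim <- (resp + 8) / (1 - pp$wastage)
  al <- allocate(assim, c(leaf = 10, stem = 6), 26, st, pp)
  expect_equal(al$ledger$sd_ratio, 0.5)
  expect_equal(al$ledger$growth_leaf, 5)
  expect_equal(al$ledger$growth_stem, 3)
  # nothing at all: no growth, respiration unpaid, stress, no negative mass
  al0 <- allocate(0, c(leaf = 10, stem = 6), 26, st, pp)
  expect_equal(al0$ledger$growth_leaf, 0)
  expect_true(al0$state$stressed)
  expect_gte(al0$state$labile, 0)
  expect_gte(al0$state$root, 0)
})

test_that("a pest-free seeded crop cycle builds yield monotonically after establishment", {
  wx <- generate_weather("humid", 1, 9)
  water <- pmin(1, cassavabc:::trailing_sum(wx$rain, pp$water_window) /
                  (pp$water_window * pp$water_demand))
  st <- new_plant(pp)
  roots <- numeric(330)
  ledger_err <- 0
  for (i in 1:330) {
    day <- list(tmax = wx$tmax[i], tmin = wx$tmin[i], rain = wx$rain[i],
                solar = wx$solar[i], rh = wx$rh[i])
    g <- grow_plant_day(st, day, water[i], 0, 0, pp)
    st <- g$state
    lg <- g$ledger
    ledger_err <- max(ledger_err,
                      abs(lg$assimilate - (lg$offtake + lg$wastage +
                        lg$respiration + lg$growth_leaf + lg$growth_stem +
                        lg$to_reserves + lg$to_root)) /
                        max(1, lg$assimilate))
    roots[i] <- root_yield(st)
  }
  expect_lt(ledger_err, 1e-9)
  expect_gt(root_yield(st), 1500)            # humid belt calibration
  expect_true(all(diff(roots[150:330]) >= -1e-9))
})

test_that("degenerate days behave: complete drain and below-threshold cold", {
  st <- new_plant(pp)
  st$leaf <- stage_state(pp$leaf_stage, 200)
  day <- list(tmax = 30, tmin = 22, rain = 0, solar = 20, rh = 60)
  res <- plant_resources(st, day, 1, pp)
  g <- grow_plant_day(st, day, 1, cm_drain = res$assim, cgm_damage = 0, pp)
  expect_equal(g$ledger$offtake, res$assim)
  expect_equal(g$ledger$growth_leaf + g$ledger$growth_stem, 0,
               tolerance = 1e-9)
  # a day entirely at the threshold: no aging, no assimilation
  cold <- list(tmax = 14.86, tmin = 10, rain = 0, solar = 18, rh = 60)
  g2 <- grow_plant_day(new_plant(pp), cold, 1, 0, 0, pp)
  expect_equal(g2$dd, 0)
  expect_equal(g2$ledger$assimilate, 0)
})

test_that("green mite damage removes leaf but never below zero", {
  st <- new_plant(pp)
  st$leaf <- stage_state(pp$leaf_stage, 50)
  day <- list(tmax = 30, tmin = 22, rain = 5, solar = 20, rh = 70)
  g <- grow_plant_day(st, day, 1, 0, cgm_damage = 1e6, pp)
  expect_gte(stage_total(g$state$leaf), 0)
  expect_lte(g$ledger$leaf_damage, 50 + g$ledger$growth_leaf + 1e-9)
})

test_that("initial state reflects the cutting and yields are reproducible", {
  st <- new_plant(pp)
  expect_equal(root_yield(st), pp$cutting_root)
  expect_equal(st$stem, pp$cutting_stem)
  expect_equal(leaf_area(st, pp), pp$cutting_leaf * pp$sla)
})
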