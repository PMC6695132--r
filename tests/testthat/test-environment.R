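# Synthetic climatology: seasonal patterns, grazing bookkeeping and
# relaxation dynamics.

test_that("seasonal forcing is periodic and internally consistent", {
  cfg <- forcing_config()
  for (d in c(1, 100, 250, 365)) {
    a <- seasonal_forcing(d, cfg)
    b <- seasonal_forcing(d + 365, cfg)
    expect_identical(a, b)
    expect_equal(a$sst, a$temperature[1])
    expect_true(all(a$microzoo >= 0) && all(a$mesozoo >= 0))
    expect_true(all(is.finite(a$temperature)))
  }
  expect_error(seasonal_forcing(0, cfg), "day_of_year")
  expect_error(seasonal_forcing(-3, cfg), "day_of_year")
})

test_that("default SST crosses the spawning thresholds in spring and autumn", {
  cfg <- forcing_config()
  sst <- seasonal_sst(1:365, cfg)
  up15 <- which(diff(sst > 15) == 1)
  down16 <- which(diff(sst < 16) == 1)
  expect_length(up15, 1)
  expect_length(down16, 1)
  expect_true(up15 >= 91 && up15 <= 121)    # mid/late April
  expect_true(down16 >= 288 && down16 <= 334)  # late Oct / Nov
})

test_that("column-mean mesozoo peaks in early summer and is low in autumn", {
  cfg <- forcing_config()
  cm <- seasonal_colmean(1:365, cfg, "meso")
  peak_day <- which.max(cm)
  expect_true(peak_day >= 135 && peak_day <= 196)  # May-July
  autumn <- 244:334  # Sep-Nov
  expect_true(all(cm[peak_day] > cm[autumn]))
  # sharp decline: autumn plateau near the seasonal minimum
  expect_lt(max(cm[autumn]) / cm[peak_day], 0.35)
})

test_that("the summer mesozoo profile has a deep maximum, winter a shallow one", {
  cfg <- forcing_config()
  aug <- seasonal_forcing(220, cfg)
  feb <- seasonal_forcing(46, cfg)
  expect_gt(aug$depth[which.max(aug$mesozoo)], cfg$z_thermo)
  expect_equal(which.max(feb$mesozoo), 1)
  # summer thermal stratification
  expect_gt(aug$temperature[1] - aug$temperature[10], 5)
  expect_lt(abs(feb$temperature[1] - feb$temperature[10]), 2)
})

test_that("grazing caps removal at availability and conserves mass", {
  cfg <- forcing_config()
  st <- seasonal_forcing(150, cfg)
  # zero demand leaves the state untouched
  g0 <- graze(st, list(micro = 0, meso = 0), cfg)
  expect_identical(g0$state, st)
  expect_error(graze(st, list(micro = -1, meso = 0), cfg), "non-negative")
  # demand twice the exposed biomass removes exactly the exposed mass:
  # the whole surface pool plus the ascended share of the deep pool
  surf <- st$depth <= cfg$z_thermo
  to_wet <- cfg$bin_volume * cfg$mgc_to_wet
  exposed <- (sum(st$mesozoo[surf]) +
                cfg$night_ascent * sum(st$mesozoo[!surf])) * to_wet
  g2 <- graze(st, list(micro = 0, meso = 2 * exposed), cfg)
  expect_equal(g2$removed$meso, exposed, tolerance = 1e-12)
  expect_equal(sum(g2$state$mesozoo[surf]), 0, tolerance = 1e-12)
  expect_equal(g2$state$mesozoo[!surf],
               st$mesozoo[!surf] * (1 - cfg$night_ascent))
  expect_equal(g2$frac$meso, 0.5, tolerance = 1e-12)
  # partial removal: removed equals the total pool-mass difference
  dem <- 0.25 * exposed
  g1 <- graze(st, list(micro = 0, meso = dem), cfg)
  removed_by_pools <- (sum(st$mesozoo) - sum(g1$state$mesozoo)) * to_wet
  expect_equal(removed_by_pools, dem, tolerance = 1e-10 * dem)
  # microzooplankton is grazed in the surface layer only
  gm <- graze(st, list(micro = 0.1 * sum(st$microzoo[surf]) * to_wet,
                       meso = 0), cfg)
  expect_equal(gm$state$microzoo[!surf], st$microzoo[!surf])
})

test_that("grazing removal equals the summed realised SI consumption", {
  # bookkeeping oracle: build a demand from explicit per-SI consumption
  cfg <- forcing_config()
  st <- seasonal_forcing(180, cfg)
  set.seed(5)
  C <- runif(20, 0, 0.2)   # specific consumption per SI
  W <- runif(20, 1, 20)
  N <- runif(20, 1e6, 1e8)
  demand <- sum(C * W * N)
  g <- graze(st, list(micro = 0, meso = demand), cfg)
  realised <- sum(C * W * N) * g$frac$meso
  expect_equal(g$removed$meso, realised, tolerance = 1e-10)
})

test_that("relaxation follows the closed-form exponential approach", {
  cfg <- forcing_config(grazing_feedback = TRUE)
  st <- seasonal_forcing(100, cfg)
  K <- seasonal_forcing(101, cfg)
  # pool already at capacity stays there (approximately: K changes by day)
  r0 <- relax_to_climatology(K, cfg, dt = 1)
  expect_equal(r0$state$mesozoo, seasonal_forcing(102, cfg)$mesozoo,
               tolerance = 0.05)
  # zeroed pool recovers as K (1 - exp(-r t))
  st0 <- st
  st0$mesozoo[] <- 0
  r1 <- relax_to_climatology(st0, cfg, dt = 1)
  expect_equal(r1$state$mesozoo,
               seasonal_forcing(101, cfg)$mesozoo *
                 (1 - exp(-cfg$relax_rate)),
               tolerance = 1e-12)
  # production diagnostic equals the pool change
  dpool <- sum(r1$state$mesozoo - st0$mesozoo) * cfg$bin_volume *
    cfg$mgc_to_wet
  expect_equal(r1$production$meso, dpool, tolerance = 1e-10)
  expect_error(relax_to_climatology(st, cfg, dt = 0), "dt")
})

test_that("zooplankton mass bookkeeping closes over a multi-year run", {
  sim <- short_run()
  bk <- sim$bookkeeping
  for (pool in c("micro", "meso")) {
    net <- bk$final[[pool]] - bk$init[[pool]]
    flux <- bk$production[[pool]] - bk$removal[[pool]]
    expect_equal(net, flux, tolerance = 1e-8 * max(abs(flux), 1))
  }
})

test_that("more fish means less equilibrium mesozooplankton", {
  lo <- run_simulation(sim_config(years = 3, spinup_years = 1,
                                  init_biomass = list(anchovy = 15000,
                                                      sardine = 10000)))
  hi <- run_simulation(sim_config(years = 3, spinup_years = 1,
                                  init_biomass = list(anchovy = 80000,
                                                      sardine = 50000)))
  d <- 366:(3 * 365)
  expect_gt(mean(lo$daily$meso_colmean[d]), mean(hi$daily$meso_colmean[d]))
})

test_that("forcing replay is deterministic", {
  cfg <- forcing_config()
  a <- precompute_climate(cfg)
  b <- precompute_climate(cfg)
  expect_identical(a, b)
})
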