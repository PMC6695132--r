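# Energy allocation, spawning rules, atresia and the capital index.

test_that("surplus allocation follows the maturity-gated k split", {
  p <- anchovy_params()  # k = 0.5, L_m = 100
  st <- new_repro_state(3)
  # immature fish grow with all surplus; W = 1 g keeps units transparent
  a <- allocate_energy(A = 10, W = 1, L = 90, st, p)
  expect_equal(a$growth[1], 10)
  expect_equal(a$state$E_buffer[1], 0)
  # mature fish split: growth 5, buffer +5
  a <- allocate_energy(A = 10, W = 1, L = 110, st, p)
  expect_equal(a$growth[1], 5)
  expect_equal(a$state$E_buffer[1], 5)
  expect_equal(a$E_buffer_alloc[1], 5)
  # deficit: buffer drained first, remainder from soma
  st$E_buffer <- rep(3, 3)
  a <- allocate_energy(A = -5, W = 1, L = 110, st, p)
  expect_equal(a$state$E_buffer[1], 0)
  expect_equal(a$state$ar_cum[1], 3)
  expect_equal(a$growth[1], -2)
  # buffer never goes negative
  expect_true(all(a$state$E_buffer >= 0))
})

test_that("deposits scale with individual weight", {
  p <- sardine_params()
  st <- new_repro_state(1)
  a <- allocate_energy(A = 0.04, W = 12, L = 120, st, p)
  expect_equal(a$state$E_buffer, (1 - p$k_alloc) * 0.04 * 12)
  expect_equal(a$growth, p$k_alloc * 0.04)
})

test_that("spawning requires gate, maturity, buffer and an open season", {
  pa <- anchovy_params(); ps <- sardine_params()
  st <- new_repro_state(1)
  st$season_open <- TRUE
  st$E_buffer <- 100
  # anchovy below its 15 C threshold never spawns
  expect_false(spawn_decision(14.9, 110, 10, st, pa))
  expect_true(spawn_decision(15.1, 110, 10, st, pa))
  # sardine spawns below 16 C
  expect_true(spawn_decision(15.5, 110, 10, st, ps))
  expect_false(spawn_decision(16.5, 110, 10, st, ps))
  # length and buffer criteria
  expect_false(spawn_decision(15.1, 99, 10, st, pa))
  poor <- st; poor$E_buffer <- 0.01
  expect_false(spawn_decision(15.1, 110, 10, poor, pa))
  closed <- st; closed$season_open <- FALSE
  expect_false(spawn_decision(15.1, 110, 10, closed, pa))
})

test_that("nine consecutive deficit days close the season for good", {
  p <- anchovy_params()
  st <- new_repro_state(1)
  st$E_buffer <- 10
  st <- season_start(st)
  # atresia terminates only a season with spawning under way
  st <- release_batch(10, 1000, st, p)$state
  for (d in 1:8) st <- update_hunger(st, TRUE, p)
  expect_true(st$season_open)
  # a sufficient day resets the counter
  st <- update_hunger(st, FALSE, p)
  expect_equal(st$hunger_days, 0L)
  for (d in 1:9) st <- update_hunger(st, TRUE, p)
  expect_false(st$season_open)
  # even abundant food afterwards does not reopen the season
  st <- update_hunger(st, FALSE, p)
  expect_false(st$season_open)
  expect_false(spawn_decision(15.5, 110, 10,
                              within(st, E_buffer <- 100), p))
  # before the first batch, hunger alone cannot close the season
  fresh <- season_start(new_repro_state(1))
  for (d in 1:20) fresh <- update_hunger(fresh, TRUE, p)
  expect_true(fresh$season_open)
})

test_that("egg batches follow daily specific fecundity", {
  pa <- anchovy_params(); ps <- sardine_params()
  st <- new_repro_state(1)
  st$E_buffer <- 10
  b <- release_batch(W = 10, N = 1000, st, pa)
  expect_equal(b$eggs_per_ind, 460)         # 46 eggs/g * 10 g
  expect_equal(b$egg_pop, 460000)
  expect_equal(b$state$E_buffer, 10 - pa$E_egg * 10)
  expect_equal(b$state$egg_cum, pa$E_egg * 10)
  b2 <- release_batch(W = 10, N = 0, st, ps)
  expect_equal(b2$eggs_per_ind, 201)        # 20.1 eggs/g * 10 g
  expect_equal(b2$egg_pop, 0)               # degenerate: empty egg SI
  # insufficient buffer signals a bookkeeping inconsistency
  broke <- new_repro_state(1)
  expect_error(release_batch(10, 1, broke, pa), "insufficient buffer")
})

test_that("capital index locates breeders on the capital-income continuum", {
  # all egg energy from the pre-season store
  expect_equal(capital_index(16, 0, 0, 16), 1.0)
  # buffer unchanged: all egg energy from concurrent intake
  expect_equal(capital_index(5, 5, 0, 16), 0.0)
  # mixed case from the definition
  expect_equal(capital_index(16, 6, 2, 16), 0.5)
  # undefined without spawning: reported missing, not zero
  expect_true(is.na(capital_index(10, 4, 0, 0)))
})

test_that("season accounting closes exactly", {
  # simulate a season of deposits, debits and emergency withdrawals
  p <- anchovy_params()
  st <- new_repro_state(1)
  st$E_buffer <- 2
  st <- season_start(st)
  set.seed(8)
  deposits <- withdrawals <- debits <- 0
  W <- 10
  for (d in 1:120) {
    A <- rnorm(1, 0.004, 0.006)
    a <- allocate_energy(A, W, 110, st, p)
    st <- a$state
    if (A >= 0) deposits <- deposits + (1 - p$k_alloc) * A * W
    st <- update_hunger(st, A < 0, p)
    if (spawn_decision(16, 110, W, st, p)) {
      b <- release_batch(W, 1, st, p)
      st <- b$state
      debits <- debits + p$E_egg * W
    }
  }
  withdrawals <- st$ar_cum
  expect_equal(st$buf_start - st$E_buffer,
               withdrawals + debits - deposits, tolerance = 1e-10)
  expect_equal(st$egg_cum, debits, tolerance = 1e-12)
  expect_true(st$E_buffer >= 0)
})

test_that("population egg release obeys each species' SST gate", {
  sim <- short_run()
  sst <- sim$daily$sst
  for (sp in c("anchovy", "sardine")) {
    p <- if (sp == "anchovy") anchovy_params() else sardine_params()
    egg_days <- which(sim$daily$eggs[, sp] > 0)
    expect_gt(length(egg_days), 30)  # both species do spawn
    expect_true(all(sst_gate_open(sst[egg_days], p)))
  }
})
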