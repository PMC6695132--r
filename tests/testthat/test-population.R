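# Super-individual population mechanics: mortality, starvation, stage
# structure, DVM and the SI-cap merge policy.

test_that("mortality integrates the exponential decay exactly", {
  expect_equal(apply_mortality(500, 0, 0, 1), 500)
  expect_equal(apply_mortality(1000, 0.4, 0, 1), 1000 * exp(-0.4))
  expect_equal(1000 * exp(-0.4), 670.32, tolerance = 1e-4)
  # adult anchovy over a year
  expect_equal(apply_mortality(1, 0.002, 0.00136, 365),
               exp(-0.00336 * 365))
  expect_error(apply_mortality(-1, 0.1), ">= 0")
  expect_error(apply_mortality(1, -0.1), ">= 0")
})

test_that("the 35% cumulative weight-loss rule kills precisely", {
  expect_true(starvation_check(10, 10))
  expect_false(starvation_check(6.4, 10))   # 36% loss: dead
  expect_true(starvation_check(6.6, 10))    # 34% loss: alive
})

test_that("embryonic duration declines smoothly with temperature", {
  p <- anchovy_params()
  expect_lt(embryonic_duration(20, p), embryonic_duration(15, p))
  T <- seq(5, 30, by = 0.1)
  D <- embryonic_duration(T, p)
  expect_true(all(D > 0))
  expect_true(all(diff(D) < 0))
  expect_true(all(abs(diff(D)) < 0.2))  # continuous, no jumps
  # default form checked against its literal formula
  expect_equal(embryonic_duration(18, p), 22.3 * exp(-0.0875 * 18),
               tolerance = 1e-12)
  expect_error(embryonic_duration(2, p), "range")
})

test_that("stage transitions respect the species length windows", {
  p <- anchovy_params()
  pop <- new_population(p)
  pop <- admit_si(pop, list(stage = 3L, N = 1e6, W = 0.5, L = 42.5,
                            age = 80), p)
  tr <- stage_transition(pop, p)
  expect_equal(tr$pop$stage[tr$pop$stage > 0], 4L)  # late larva -> juvenile
  ps <- sardine_params()
  pop2 <- new_population(ps)
  pop2 <- admit_si(pop2, list(stage = 4L, N = 1e5,
                              W = weight_from_length(106, ps), L = 106,
                              age = 330), ps)
  tr2 <- stage_transition(pop2, ps)
  expect_equal(tr2$pop$stage[tr2$pop$stage > 0], 5L)  # adult age-1
  expect_equal(tr2$newly_adult, which(tr2$pop$stage == 5L))
})

test_that("terminal adult classes die at class end; sardine lives a year longer", {
  pa <- anchovy_params()
  pop <- new_population(pa)
  pop <- admit_si(pop, list(stage = 7L, N = 1e5, W = 30, L = 150,
                            age = 4 * 365 + 1), pa)
  tr <- stage_transition(pop, pa)
  expect_equal(sum(tr$pop$stage > 0), 0)  # age past class 3: senescent
  ps <- sardine_params()
  pop2 <- new_population(ps)
  pop2 <- admit_si(pop2, list(stage = 8L, N = 1e5, W = 40, L = 170,
                              age = 4 * 365 + 1), ps)
  tr2 <- stage_transition(pop2, ps)
  expect_equal(sum(tr2$pop$stage > 0), 1)  # sardine age-4 persists
})

test_that("diel vertical migration places stages in the right layer", {
  expect_equal(dvm_layer("embryo", 12), "surface")
  expect_equal(dvm_layer("early", 12), "surface")
  expect_equal(dvm_layer("adult", 12), "deep")
  expect_equal(dvm_layer("adult", 0), "surface")
  expect_equal(dvm_layer("late", 23), "surface")
  expect_equal(dvm_layer("juvenile", 9), "deep")
})

test_that("SI merging conserves abundance and biomass", {
  p <- anchovy_params()
  pop <- new_population(p)
  pop <- admit_si(pop, list(stage = 4L, N = 100, W = 1, L = 50), p)
  pop <- admit_si(pop, list(stage = 4L, N = 300, W = 2, L = 60), p)
  m <- pelagibm:::merge_si(pop, 1L, 2L)
  expect_equal(m$N[1], 400)
  expect_equal(m$W[1], 1.75)        # abundance-weighted mean
  expect_equal(m$stage[2], 0L)
  expect_equal(sum(m$N * m$W), 100 * 1 + 300 * 2)  # biomass conserved
})

test_that("admitting past the cap merges the smallest incumbent", {
  p <- anchovy_params()
  pop <- new_population(p)
  set.seed(2)
  for (i in 1:10)  # juvenile cap is 10
    pop <- admit_si(pop, list(stage = 4L, N = 1000 + 100 * i,
                              W = 0.5 + 0.1 * i, L = 45 + i), p)
  before_N <- sum(pop$N)
  before_B <- sum(pop$N * pop$W)
  pop <- admit_si(pop, list(stage = 4L, N = 500, W = 1.2, L = 55), p)
  expect_equal(sum(pop$stage == 4L), 10)
  expect_equal(sum(pop$N), before_N + 500, tolerance = 1e-10)
  expect_equal(sum(pop$N * pop$W), before_B + 500 * 1.2,
               tolerance = 1e-10 * before_B)
  # below the cap nothing is merged
  pop2 <- new_population(p)
  pop2 <- admit_si(pop2, list(stage = 2L, N = 10, W = 0.001, L = 5), p)
  expect_equal(sum(pop2$stage == 2L), 1)
})

test_that("abundance is exactly conserved without mortality or spawning", {
  # impossible SST gates (no spawning), zero mortality everywhere, and
  # adults seeded young enough that nobody leaves the terminal age class
  pa <- anchovy_params(M = c(embryo = 0, early = 0, late = 0,
                             juvenile = 0, adult = 0),
                       F_adult = 0, sst_threshold = 99)
  ps <- sardine_params(M = c(embryo = 0, early = 0, late = 0,
                             juvenile = 0, adult = 0),
                       F_adult = 0, sst_threshold = -99)
  pops <- lapply(list(anchovy = pa, sardine = ps), function(p) {
    pop <- new_population(p)
    for (a in 1:2)
      pop <- admit_si(pop, list(stage = 4L + a, N = 1e8 / a,
                                W = weight_from_length(
                                  p$init_lengths[a], p),
                                L = p$init_lengths[a],
                                age = a * 365 + 5, veteran = TRUE), p)
    pop
  })
  cf <- sim_config(species = list(anchovy = pa, sardine = ps),
                   years = 1, spinup_years = 0)
  sim <- run_simulation(cf, pops = pops)
  for (sp in c("anchovy", "sardine"))
    expect_equal(sum(sim$pops[[sp]]$N), 1e8 + 5e7, tolerance = 1e-10)
})

test_that("per-stage SI counts never exceed their caps in a coupled run", {
  sim <- short_run()
  for (sp in c("anchovy", "sardine")) {
    p <- sim$config$species[[sp]]
    pop <- sim$pops[[sp]]
    counts <- tabulate(pop$stage, nbins = p$n_stages)
    expect_true(all(counts <= pelagibm:::stage_caps(p)))
    # stage residency respects the length windows (with one day's growth
    # of slack at the upper boundaries)
    win <- p$length_windows
    for (s in 2:4) {
      L <- pop$L[pop$stage == s]
      if (length(L)) expect_true(all(L < win[s] * 1.25))
    }
    expect_true(all(pop$W_max_seen[pop$stage > 0] >=
                      pop$W[pop$stage > 0] * (1 - 1e-12)))
  }
})
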