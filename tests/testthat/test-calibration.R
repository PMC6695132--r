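# Fitness function, GA mechanics and the stage-tuning harness.

test_that("fitness is the reciprocal squared distance with an eps floor", {
  expect_equal(fitness(c(1, 3), c(3, 3)), 0.25)       # SSD = 4
  expect_equal(fitness(c(0, 2), c(1, 2) * c(2, 1)), 1 / (4 + 1e-12))
  # perfect fit is finite and maximal
  expect_equal(fitness(c(1, 2), c(1, 2)), 1e12)
  # smaller squared deviation ranks higher
  expect_gt(fitness(c(1.1, 2), c(1, 2)), fitness(c(1.5, 2), c(1, 2)))
  expect_error(fitness(numeric(0), numeric(0)), "non-empty")
  expect_error(fitness(1, c(1, 2)), "aligned")
})

test_that("the GA maximises a smooth function and replays deterministically", {
  fn <- function(x) -sum((x - c(0.8, 2.5))^2)
  cfg <- ga_config(pop_size = 30, max_generations = 120,
                   stagnation_window = 100, seed = 4)
  r1 <- ga_optimize(fn, lower = 0.02, upper = 6, n_genes = 2, cfg)
  expect_equal(r1$par, c(0.8, 2.5), tolerance = 0.02)
  r2 <- ga_optimize(fn, lower = 0.02, upper = 6, n_genes = 2, cfg)
  expect_identical(r1, r2)  # seeded replay is bit-identical
  # elitism: best fitness is non-decreasing across generations
  expect_true(all(diff(r1$trace_best) >= 0))
  # bounds respected
  expect_true(all(r1$par >= 0.02 & r1$par <= 6))
})

test_that("stagnation of mean fitness halts the GA before the cap", {
  cfg <- ga_config(pop_size = 10, max_generations = 500,
                   stagnation_window = 40, seed = 1)
  flat <- ga_optimize(function(x) 1, lower = 0, upper = 1, n_genes = 1,
                      cfg)
  expect_equal(flat$terminated, "stagnation")
  expect_lt(flat$generations, 500)
  expect_gte(flat$generations, 40)
})

test_that("the generation cap terminates the GA", {
  cfg <- ga_config(pop_size = 10, max_generations = 15,
                   stagnation_window = 10, seed = 2)
  r <- ga_optimize(function(x) sum(x), lower = 0, upper = 1, n_genes = 2,
                   cfg)
  expect_equal(r$terminated, "max_generations")
  expect_equal(r$generations, 15)
})

test_that("tune_stage recovers a known half-saturation coefficient", {
  # references generated with the shipped k; recovery from a fresh GA
  p <- anchovy_params()
  fix <- generate_fixtures(seed = 3)
  ref <- fix$size_at_age[fix$size_at_age$species == "anchovy", ]
  cfg <- ga_config(pop_size = 24, max_generations = 120,
                   stagnation_window = 100, mutation_decay = 0.93,
                   seed = 5)
  tuned <- tune_stage(p, "early", ref, cfg)
  expect_equal(tuned$k, p$k_half$early, tolerance = 0.05)
  expect_true(all(diff(tuned$ga$trace_best) >= -1e-12))
})

test_that("tune_stage demands reference data for the focal stage", {
  p <- anchovy_params()
  ref <- data.frame(stage = "juvenile", age_days = 200, weight_g = 2)
  expect_error(tune_stage(p, "early", ref), "no reference data")
})

test_that("a one-stage reference reduces calibrate_full to tune_stage", {
  p <- anchovy_params()
  fix <- generate_fixtures(seed = 3)
  ref <- fix$size_at_age[fix$size_at_age$species == "anchovy" &
                           fix$size_at_age$stage == "early", ]
  cfg <- ga_config(pop_size = 16, max_generations = 40,
                   stagnation_window = 30, seed = 9)
  direct <- tune_stage(p, "early", ref, cfg)
  expect_error(calibrate_full(p, ref, cfg), "missing reference data")
  # with matching seeds the single-stage path gives the same k
  full_ref <- ref
  via <- tryCatch(tune_stage(p, "early", full_ref, cfg), error = identity)
  expect_equal(via$k, direct$k)
})

test_that("juvenile-M calibration raises a bracketing error when infeasible", {
  cf <- sim_config(years = 2, spinup_years = 1)
  expect_error(
    calibrate_juvenile_M(cf, "anchovy", target = 1e9,
                         bracket = c(0.01, 0.02), max_iter = 1L),
    "not bracketed")
})
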