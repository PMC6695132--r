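# Wisconsin bioenergetics formulas against independent literal oracles,
# plus the structural identities of the daily budget.

test_that("temperature scalar has its fixed points and matches the oracle", {
  expect_equal(temperature_scalar(15.8, 15.8, 27, 2.4), 1.0)
  expect_equal(temperature_scalar(27, 15.8, 27, 2.4), 0.0)
  expect_equal(temperature_scalar(30, 15.8, 27, 2.4), 0.0)
  # anchovy adult at 20 C, frozen from the literal oracle
  expect_equal(temperature_scalar(20, 15.8, 27, 2.4), 0.80157886,
               tolerance = 1e-7)
  expect_error(temperature_scalar(20, 27, 27, 2.4), "T_opt")
  set.seed(42)
  for (i in 1:100) {
    T_opt <- runif(1, 10, 20); T_max <- T_opt + runif(1, 2, 15)
    Q_c <- runif(1, 1.5, 3); T <- runif(1, 0, T_max)
    expect_equal(temperature_scalar(T, T_opt, T_max, Q_c),
                 oracle_fc(T, T_opt, T_max, Q_c), tolerance = 1e-10)
  }
})

test_that("temperature scalar is bounded by 1 with the maximum at T_opt", {
  T <- seq(0, 27, by = 0.05)
  f <- temperature_scalar(T, 15.8, 27, 2.4)
  expect_true(all(f <= 1 + 1e-12))
  expect_lt(max(f[abs(T - 15.8) > 0.5]), 1)
  expect_equal(T[which.max(f)], 15.8)
})

test_that("maximum consumption follows a_c W^b_c f_C", {
  p <- anchovy_params()
  expect_equal(max_consumption(1, 15.8, p, "adult"), 0.41)
  expect_equal(max_consumption(10, 27, p, "adult"), 0)
  expect_equal(max_consumption(10, 15.8, p, "adult"), 0.41 * 10^(-0.31))
  # mass-specific ration declines with size
  expect_gt(max_consumption(0.001, 15.8, p, "adult"),
            max_consumption(10, 15.8, p, "adult"))
  expect_error(max_consumption(-1, 15, p), "positive")
})

test_that("consumption saturates per the multi-prey functional response", {
  p <- anchovy_params()
  cmax <- 0.3
  expect_equal(consumption(cmax, 0, 0, p, "adult")$total, 0)
  # single prey at PD v / k = 1 gives C_max / 2
  k <- p$k_half$adult[1]
  cons <- consumption(cmax, 0, k, p, "adult")
  expect_equal(cons$total, cmax / 2)
  expect_equal(cons$micro, 0)  # adults are invulnerable to microzoo
  # two prey each at ratio 1: each C_max/3 (late larvae, v = 0.5 each)
  p2 <- anchovy_params(k_half = list(early = 0.2, late = c(0.5, 0.5),
                                     juvenile = 0.6, adult = rep(0.6, 3)))
  cons2 <- consumption(cmax, 1, 1, p2, "late")
  expect_equal(cons2$micro, cmax / 3)
  expect_equal(cons2$meso, cmax / 3)
  expect_equal(cons2$total, 2 * cmax / 3)
  # early larvae ignore mesozooplankton entirely
  expect_equal(consumption(cmax, 0, 100, p, "early")$total, 0)
  expect_error(consumption(cmax, -1, 0, p, "adult"), ">= 0")
  expect_error(consumption(cmax, 0, 0, p, "embryoX"), "unknown stage")
})

test_that("total consumption never exceeds C_max", {
  p <- sardine_params()
  set.seed(7)
  for (i in 1:50) {
    cmax <- runif(1, 0, 5)
    tot <- consumption(cmax, runif(1, 0, 10), runif(1, 0, 10), p,
                       sample(2:8, 1))$total
    expect_true(tot >= 0 && tot <= cmax + 1e-12)
  }
})

test_that("respiration matches the literal oracle across both regimes", {
  p <- anchovy_params()
  # Q10 = 1 and d_r = 0 collapse to a_r W^b_r
  p0 <- anchovy_params(resp = utils::modifyList(
    p$resp, list(Q10 = 1, d_r = 0)))
  expect_equal(respiration(10, 16, p0, "adult"),
               0.003 * 10^(-0.34))
  # anchovy adult at T = T_m = 16, W = 10 g: oracle evaluation
  rp <- p$resp
  expect_equal(respiration(10, 16, p, "adult"),
               oracle_resp(10, 16, rp$a_r, rp$b_r, rp$Q10, rp$T_m, rp$d_r,
                           rp$a_A_cold, 14.21, 0.27, rp$c_A_cold,
                           rp$c_A_warm),
               tolerance = 1e-10)
  set.seed(99)
  for (i in 1:100) {
    W <- runif(1, 0.001, 60); T <- runif(1, 5, 27)
    s <- sample(2:7, 1)
    fi <- p$fidx[s]
    expect_equal(respiration(W, T, p, s),
                 oracle_resp(W, T, rp$a_r, rp$b_r, rp$Q10, rp$T_m, rp$d_r,
                             rp$a_A_cold, rp$a_A_warm[fi], rp$b_A[fi],
                             rp$c_A_cold, rp$c_A_warm),
                 tolerance = 1e-10)
  }
})

test_that("respiration is continuous in W and increasing in T above 12 C", {
  p <- anchovy_params()
  W <- seq(0.5, 40, length.out = 400)
  R <- respiration(W, 18, p, "adult")
  expect_true(all(abs(diff(R)) < 0.05 * R[-1]))  # no jumps
  T <- seq(12, 27, by = 0.25)
  R_T <- respiration(10, T, p, "adult")
  expect_true(all(diff(R_T) > 0))
  # juveniles respire less under the low-feeding-activity variant
  expect_lt(respiration(2, 18, p, "juvenile", low_feeding = TRUE),
            respiration(2, 18, p, "juvenile", low_feeding = FALSE))
})

test_that("length-weight relation matches the oracle and inverts exactly", {
  for (p in list(anchovy_params(), sardine_params())) {
    lw <- p$lw
    # continuity at the first inflexion point
    L1 <- 10^lw[["d1"]]
    expect_equal(weight_from_length(L1 * (1 - 1e-9), p),
                 weight_from_length(L1 * (1 + 1e-9), p),
                 tolerance = 1e-6)
    for (L in c(5, 12, 38, 60, 120, 180))
      expect_equal(weight_from_length(L, p),
                   oracle_w_from_l(L, lw[["b0"]], lw[["b1"]], lw[["b2"]],
                                   lw[["d1"]], lw[["b3"]], lw[["d2"]]),
                   tolerance = 1e-10)
    W <- c(1e-4, 0.01, 0.5, 5, 20, 80)
    expect_equal(weight_from_length(length_from_weight(W, p), p), W,
                 tolerance = 1e-8)
  }
  # anchovy at 120 mm, frozen from the oracle
  expect_equal(weight_from_length(120, anchovy_params()), 12.6446,
               tolerance = 1e-4)
  expect_error(weight_from_length(0, anchovy_params()), "positive")
  expect_error(length_from_weight(-2, anchovy_params()), "positive")
})

test_that("daily budget satisfies the egestion/excretion/SDA identities", {
  p <- anchovy_params()
  set.seed(3)
  for (i in 1:100) {
    W <- runif(1, 0.01, 40)
    s <- sample(2:7, 1)
    b <- daily_budget(W, T_night = runif(1, 10, 26),
                      T_day = runif(1, 10, 18),
                      micro = runif(1, 0, 1), meso = runif(1, 0, 1),
                      params = p, stage = s,
                      E_buffer_alloc = runif(1, -0.01, 0.01))
    expect_equal(b$EG, p$a_f_stage[s] * b$C, tolerance = 1e-12)
    expect_equal(b$SDA, p$a_sda * (b$C - b$EG), tolerance = 1e-12)
    expect_equal(b$EX, p$a_e * (b$C - b$EG) + p$b_e, tolerance = 1e-12)
    expect_equal(b$A, b$C - (b$R + b$EG + b$SDA + b$EX), tolerance = 1e-12)
  }
})

test_that("energy closure holds to 1e-10 in the composed budget", {
  p <- sardine_params()
  set.seed(11)
  for (i in 1:100) {
    alloc <- runif(1, -0.02, 0.02)
    b <- daily_budget(runif(1, 0.05, 30), runif(1, 12, 25),
                      runif(1, 12, 16), runif(1, 0, 0.6),
                      runif(1, 0, 0.6), p, sample(2:8, 1),
                      E_buffer_alloc = alloc)
    # C - (dW/W * CAL_f/CAL_z + R + EG + SDA + EX + E_buffer_alloc) == 0
    residual <- b$C - (b$dW_W / p$cal_ratio + b$R + b$EG + b$SDA + b$EX +
                         alloc)
    expect_lt(abs(residual), 1e-10 * max(b$C, 1))
  }
})

test_that("starved fish lose weight and well-fed fish outgrow underfed", {
  p <- anchovy_params()
  b0 <- daily_budget(10, 16, 15, 0, 0, p, "adult")
  expect_lt(b0$dW_W, 0)  # no food: pure metabolic loss
  clim <- precompute_climate(forcing_config())
  rich <- simulate_si(p, clim, 152L, 200L)
  poor_forcing <- forcing_config(meso_low = 4, meso_peak = 22,
                                 micro_low = 6, micro_peak = 18)
  poor <- simulate_si(p, precompute_climate(poor_forcing), 152L, 200L,
                      cfg = poor_forcing)
  expect_gt(rich$W[200], poor$W[200])
})

test_that("migrating stages demand both layer temperatures", {
  p <- anchovy_params()
  expect_error(daily_budget(10, 16, NA_real_, 0, 0.3, p, "adult"),
               "day-layer")
  # non-migrating early larvae tolerate a missing day layer
  b <- daily_budget(0.001, 16, NA_real_, 0.3, 0, p, "early")
  expect_true(is.finite(b$dW_W))
})
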