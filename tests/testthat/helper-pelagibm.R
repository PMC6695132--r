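# Shared helpers: independent literal-evaluation oracles for the
# bioenergetics formulas (kept deliberately separate from the package
# implementation) and a cache for expensive shared simulations.

# --- independent formula oracles -------------------------------------------

# temperature scalar, literal transcription
oracle_fc <- function(T, T_opt, T_max, Q_c) {
  if (T >= T_max) return(0)
  S <- log(Q_c) * (T_max - T_opt)
  Y <- log(Q_c) * (T_max - T_opt + 2)
  X <- S^2 * (1 + (1 + 40 / Y)^0.5)^2 / 400
  V <- (T_max - T) / (T_max - T_opt)
  V^X * exp(X * (1 - V))
}

# respiration, literal transcription (a_A/c_A regime switch at 12 C)
oracle_resp <- function(W, T, a_r, b_r, Q10, T_m, d_r, a_A_cold, a_A_warm,
                        b_A, c_A_cold, c_A_warm) {
  a_A <- if (T < 12) a_A_cold else a_A_warm
  c_A <- if (T < 12) c_A_cold else c_A_warm
  U <- a_A * W^b_A * exp(c_A * T)
  a_r * W^b_r * Q10^((T - T_m) / 10) * exp(d_r * U)
}

# piecewise length-weight, literal transcription (base-10 logs)
oracle_w_from_l <- function(L, b0, b1, b2, d1, b3, d2) {
  x <- log10(L)
  y <- b0 + b1 * x
  if (x > d1) y <- y + b2 * (x - d1)
  if (x > d2) y <- y + b3 * (x - d2)
  10^y
}

# --- cached expensive fixtures ---------------------------------------------

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# a small coupled run shared by several structural tests
short_run <- function() cached("short_run", {
  run_simulation(sim_config(years = 4, spinup_years = 2))
})
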