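# Wisconsin-type bioenergetics: weight-specific consumption, respiration,
# egestion, excretion and specific dynamic action, all in
# g prey (g fish)^-1 d^-1, and the piecewise log-log length-weight
# relationship.  The daily weight update is
#   dW/W = [C - (R + EG + SDA + EX + E_buffer)] * CAL_z / CAL_f
# where E_buffer is the specific energy routed to (or drawn from) the
# reproductive buffer.

# Resolve a stage argument (integer stage code >= 2 or one of
# "early", "late", "juvenile", "adult") to integer stage codes.
#' @keywords internal
stage_code <- function(stage, params) {
  if (is.character(stage)) {
    m <- c(early = 2L, late = 3L, juvenile = 4L, adult = 5L)
    bad <- !stage %in% names(m)
    if (any(bad)) stop("unknown stage: ", paste(stage[bad], collapse = ", "))
    stage <- m[stage]
  }
  stage <- as.integer(stage)
  if (any(stage < 2L | stage > params$n_stages))
    stop("stage code out of range for ", params$name)
  stage
}

#' Temperature dependence of consumption
#'
#' Thornton-Lesem scalar `f_C(T) = V^X exp(X (1 - V))` with
#' `V = (T_max - T) / (T_max - T_opt)`, `S = ln(Q_c) (T_max - T_opt)`,
#' `Y = ln(Q_c) (T_max - T_opt + 2)` and
#' `X = S^2 (1 + sqrt(1 + 40 / Y))^2 / 400`.  Equals 1 at `T = T_opt`,
#' 0 at `T >= T_max`.
#'
#' @param T temperature, C (vectorised).
#' @param T_opt optimum temperature, C.
#' @param T_max maximum temperature, C (`T_opt < T_max` required).
#' @param Q_c temperature-dependence slope.
#' @return value in `[0, 1]`.
#' @export
#' @examples
#' temperature_scalar(15.8, 15.8, 27, 2.4)  # 1 at the optimum
#' temperature_scalar(27, 15.8, 27, 2.4)    # 0 at the maximum
temperature_scalar <- function(T, T_opt, T_max, Q_c) {
  if (any(T_opt >= T_max)) stop("T_opt must be below T_max")
  S <- log(Q_c) * (T_max - T_opt)
  Y <- log(Q_c) * (T_max - T_opt + 2)
  X <- S^2 * (1 + sqrt(1 + 40 / Y))^2 / 400
  V <- (T_max - T) / (T_max - T_opt)
  out <- ifelse(T >= T_max, 0, V^X * exp(X * (1 - V)))
  pmin(pmax(out, 0), 1)
}

#' Maximum weight-specific consumption
#'
#' `C_max = a_c W^{b_c} f_C(T)` in g prey (g fish)^-1 d^-1.  With the
#' default `a_c = 0.41`, `b_c = -0.31`, mass-specific maximum ration
#' declines allometrically from several g/g/d in first-feeding larvae to
#' about 0.2 g/g/d in adults.
#'
#' @param W wet weight, g (> 0; vectorised).
#' @param T experienced temperature, C.
#' @param params a [species_params()] object.
#' @param stage stage code or name (determines `T_opt` and `Q_c`).
#' @return maximum specific consumption, g prey g^-1 d^-1.
#' @export
max_consumption <- function(W, T, params, stage = "adult") {
  if (any(W <= 0)) stop("W must be positive")
  s <- stage_code(stage, params)
  fc <- temperature_scalar(T, params$T_opt_stage[s], params$T_max,
                           params$Q_c_stage[s])
  params$a_c * W^params$b_c * fc
}

#' Multi-prey consumption with half-saturation control
#'
#' `C_i = C_max (PD_i v_i / k_i) / (1 + sum_j PD_j v_j / k_j)` over the two
#' prey types (microzooplankton, mesozooplankton).  Stage-prey pairs with
#' vulnerability 0 contribute nothing: early larvae take only
#' microzooplankton, late larvae both at v = 0.5, juveniles and adults
#' only mesozooplankton.
#'
#' @param C_max maximum specific consumption (from [max_consumption()]).
#' @param micro,meso prey densities, g wet prey m^-3 (>= 0).
#' @param params a [species_params()] object.
#' @param stage stage code or name (k for adults is age-class specific).
#' @return list with `micro`, `meso` and `total` specific consumption.
#' @export
consumption <- function(C_max, micro, meso, params, stage) {
  if (any(micro < 0) || any(meso < 0)) stop("prey densities must be >= 0")
  s <- stage_code(stage, params)
  r1 <- micro * params$v_micro[s] / params$k_micro[s]
  r2 <- meso * params$v_meso[s] / params$k_meso[s]
  den <- 1 + r1 + r2
  list(micro = C_max * r1 / den,
       meso = C_max * r2 / den,
       total = C_max * (r1 + r2) / den)
}

#' Weight-specific respiration
#'
#' `R = a_r W^{b_r} f_R(T) A` with `f_R = Q10^{(T - T_m)/10}` and the
#' swimming-activity multiplier `A = exp(d_r U)`,
#' `U = a_A W^{b_A} exp(c_A T)` (U in cm s^-1).  The `(a_A, c_A)` pair
#' switches at 12 C; juveniles use a reduced `a_A` during the low-food
#' season when `low_feeding` is set.
#'
#' @param W wet weight, g (> 0; vectorised).
#' @param T experienced temperature, C.
#' @param params a [species_params()] object.
#' @param stage stage code or name.
#' @param low_feeding logical: apply the low-feeding-activity `a_A`
#'   variant (juveniles only).
#' @return specific respiration, g prey g^-1 d^-1 equivalent.
#' @export
respiration <- function(W, T, params, stage = "adult", low_feeding = FALSE) {
  if (any(W <= 0)) stop("W must be positive")
  s <- stage_code(stage, params)
  rp <- params$resp
  warm <- T >= 12
  a_A <- ifelse(warm, params$a_A_stage[s], rp$a_A_cold)
  if (any(low_feeding))
    a_A <- ifelse(warm & low_feeding & params$fidx[s] == 3L,
                  rp$a_A_lowfeed, a_A)
  c_A <- ifelse(warm, rp$c_A_warm, rp$c_A_cold)
  U <- a_A * W^params$b_A_stage[s] * exp(c_A * T)
  act <- exp(rp$d_r * U)
  rp$a_r * W^rp$b_r * rp$Q10^((T - rp$T_m) / 10) * act
}

#' Daily energy budget of a feeding fish
#'
#' Assembles consumption (evaluated with the night-layer prey field and
#' temperature, where feeding takes place), respiration (at the
#' day/night residence-time-weighted temperature), egestion
#' `EG = a_f C`, specific dynamic action `SDA = a_sda (C - EG)`,
#' excretion `EX = a_e (C - EG) + b_e`, the surplus after maintenance
#' `A = C - (R + EG + SDA + EX)` and the realised relative growth
#' `dW/W = (A - E_buffer_alloc) CAL_z / CAL_f`.
#'
#' @param W wet weight, g.
#' @param T_night,T_day night (surface) and day (sub-thermocline) layer
#'   temperatures, C.  Non-migrating stages (eggs, early larvae) should
#'   pass the surface temperature for both.
#' @param micro,meso night-layer prey densities, g wet m^-3.
#' @param params a [species_params()] object.
#' @param stage stage code or name.
#' @param E_buffer_alloc specific energy routed to the reproductive buffer
#'   (positive) or drawn from it for emergency maintenance (negative),
#'   g prey g^-1 d^-1.
#' @param day_fraction fraction of the day spent in the day layer.
#' @param consumption_scale multiplier in `[0, 1]` applied to desired
#'   consumption (prey-availability capping from [graze()]), per prey
#'   type: list(micro=, meso=).
#' @param low_feeding see [respiration()].
#' @return list (one element per budget term, each vectorised like `W`)
#'   with `C_micro`, `C_meso`, `C`, `R`, `EG`, `SDA`, `EX`, `A`, `dW_W`.
#' @export
daily_budget <- function(W, T_night, T_day, micro, meso, params, stage,
                         E_buffer_alloc = 0, day_fraction = 0.5,
                         consumption_scale = list(micro = 1, meso = 1),
                         low_feeding = FALSE) {
  s <- stage_code(stage, params)
  migrant <- params$fidx[s] >= 2L  # late larvae, juveniles, adults
  if (any(migrant & !is.finite(T_day)))
    stop("day-layer temperature required for vertically migrating stages")
  if (any(!is.finite(T_night)))
    stop("night-layer temperature required")
  cmax <- max_consumption(W, T_night, params, s)
  cons <- consumption(cmax, micro, meso, params, s)
  C_micro <- cons$micro * consumption_scale$micro
  C_meso <- cons$meso * consumption_scale$meso
  C <- C_micro + C_meso
  T_resp <- ifelse(migrant,
                   day_fraction * T_day + (1 - day_fraction) * T_night,
                   T_night)
  R <- respiration(W, T_resp, params, s, low_feeding)
  EG <- params$a_f_stage[s] * C
  SDA <- params$a_sda * (C - EG)
  EX <- params$a_e * (C - EG) + params$b_e
  A <- C - (R + EG + SDA + EX)
  list(C_micro = C_micro, C_meso = C_meso, C = C, R = R, EG = EG,
       SDA = SDA, EX = EX, A = A,
       dW_W = (A - E_buffer_alloc) * params$cal_ratio)
}

#' Length-weight conversions
#'
#' Piecewise log10-log10 length-weight relationship
#' `y = b0 + b1 x + b2 (x - d1) I(x > d1) + b3 (x - d2) I(x > d2)` with
#' `x = log10(length mm)`, `y = log10(weight g)`; continuous at the two
#' inflexion points and strictly increasing, so the two conversions are
#' mutual inverses.
#'
#' @param L length, mm (> 0; vectorised).
#' @param W wet weight, g (> 0; vectorised).
#' @param params a [species_params()] object (uses `params$lw`).
#' @return weight in g, or length in mm.
#' @export
#' @examples
#' p <- anchovy_params()
#' weight_from_length(100, p)                       # ~6.5 g at maturity
#' length_from_weight(weight_from_length(100, p), p)
weight_from_length <- function(L, params) {
  if (any(L <= 0)) stop("length must be positive")
  lw <- params$lw
  x <- log10(L)
  y <- lw["b0"] + lw["b1"] * x +
    lw["b2"] * (x - lw["d1"]) * (x > lw["d1"]) +
    lw["b3"] * (x - lw["d2"]) * (x > lw["d2"])
  unname(10^y)
}

#' @rdname weight_from_length
#' @export
length_from_weight <- function(W, params) {
  if (any(W <= 0)) stop("weight must be positive")
  lw <- params$lw
  s1 <- lw["b1"]; s2 <- lw["b1"] + lw["b2"]; s3 <- s2 + lw["b3"]
  if (s1 <= 0 || s2 <= 0 || s3 <= 0)
    stop("length-weight relation is not invertible (non-positive slope)")
  y1 <- lw["b0"] + lw["b1"] * lw["d1"]
  y2 <- y1 + s2 * (lw["d2"] - lw["d1"])
  y <- log10(W)
  x <- ifelse(y <= y1, (y - lw["b0"]) / s1,
       ifelse(y <= y2, lw["d1"] + (y - y1) / s2,
              lw["d2"] + (y - y2) / s3))
  unname(10^x)
}
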