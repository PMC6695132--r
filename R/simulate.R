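# The coupled forward simulator: a daily time-stepping loop over the two
# super-individual populations and the water-column environment.  Each day:
# plankton pools relax toward the seasonal climatology, fish consumption
# demand is aggregated and grazed from the surface layer (capping realised
# consumption at availability), individual budgets and energy allocation
# are applied, spawning and atresia rules are evaluated, mortality thins
# abundances, and stage transitions / SI caps are processed.
#
# Rates in the bioenergetics are per day, so the native daily step
# integrates one day per iteration ("daily-step mode"); this is the mode
# used throughout the package's tests and analyses.

#' @keywords internal
MONTH_LEN <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
#' @keywords internal
MONTH_START <- cumsum(c(0L, MONTH_LEN[-12])) + 1L

#' Days of year covered by a 2.5-month closure window
#'
#' The window runs from day 15 of month `m` through the last day of month
#' `m + 2` (wrapping over the year end), matching a closure "scheduled
#' between 15 December and end of February" for `m = 12`.
#'
#' @param m starting month index, 1-12.
#' @return integer vector of days of year (365-day calendar).
#' @export
closure_days <- function(m) {
  stopifnot(m >= 1, m <= 12)
  start <- MONTH_START[m] + 14L
  end_month <- ((m + 1L) %% 12L) + 1L
  end <- MONTH_START[end_month] + MONTH_LEN[end_month] - 1L
  len <- ((end - start) %% 365L) + 1L
  ((start + seq_len(len) - 2L) %% 365L) + 1L
}

#' Precompute the daily climatology tables
#'
#' Evaluates the synthetic climatology once per day of year: layer
#' temperatures, SST, carrying-capacity profiles and the juvenile
#' low-feeding-season flag (column-mean mesozooplankton below
#' `lowfeed_frac` of its annual peak).
#'
#' @param cfg a [forcing_config()].
#' @return list of per-day vectors/matrices used by the simulators.
#' @export
precompute_climate <- function(cfg) {
  n <- 365L
  nb <- cfg$n_bins
  K_micro <- matrix(0, nb, n)
  K_meso <- matrix(0, nb, n)
  temp <- matrix(0, nb, n)
  sst <- T_surf <- T_deep <- numeric(n)
  surf <- cfg$depth <= cfg$z_thermo
  for (d in seq_len(n)) {
    st <- seasonal_forcing(d, cfg)
    K_micro[, d] <- st$microzoo
    K_meso[, d] <- st$mesozoo
    temp[, d] <- st$temperature
    sst[d] <- st$sst
    T_surf[d] <- mean(st$temperature[surf])
    T_deep[d] <- mean(st$temperature[!surf])
  }
  meso_cm <- colMeans(K_meso)
  list(K_micro = K_micro, K_meso = K_meso, temp = temp, sst = sst,
       T_surf = T_surf, T_deep = T_deep, surf = surf,
       micro_surf = colMeans(K_micro[surf, , drop = FALSE]),
       meso_surf = colMeans(K_meso[surf, , drop = FALSE]),
       meso_night = (colSums(K_meso[surf, , drop = FALSE]) +
                       cfg$night_ascent *
                         colSums(K_meso[!surf, , drop = FALSE])) /
         sum(surf),
       lowfeed = meso_cm < cfg$lowfeed_frac * max(meso_cm))
}

# Per-species, per-(stage, day-of-year) lookup tables for the
# temperature-dependent factors of the daily budget; single source of
# truth is the exported formula functions.
#' @keywords internal
species_tables <- function(p, clim, cfg) {
  ns <- p$n_stages
  doys <- seq_len(365L)
  Ts <- clim$T_surf
  Tresp_mig <- cfg$day_fraction * clim$T_deep +
    (1 - cfg$day_fraction) * clim$T_surf
  fc <- matrix(0, ns, 365L)
  q10 <- matrix(0, ns, 365L)
  aA <- matrix(0, ns, 365L)      # a_A * exp(c_A T), regime-resolved
  rp <- p$resp
  for (s in 2:ns) {
    Tr <- if (s >= 3L) Tresp_mig else Ts
    fc[s, ] <- temperature_scalar(Ts, p$T_opt_stage[s], p$T_max,
                                  p$Q_c_stage[s])
    q10[s, ] <- rp$Q10^((Tr - rp$T_m) / 10)
    warm <- Tr >= 12
    base_aA <- ifelse(warm, p$a_A_stage[s], rp$a_A_cold)
    if (p$fidx[s] == 3L)
      base_aA <- ifelse(warm & clim$lowfeed, rp$a_A_lowfeed, base_aA)
    cA <- ifelse(warm, rp$c_A_warm, rp$c_A_cold)
    aA[s, ] <- base_aA * exp(cA * Tr)
  }
  list(fc = fc, q10 = q10, aA = aA)
}

#' Simulation configuration
#'
#' @param species named list of [species_params()] objects (default
#'   anchovy and sardine).
#' @param forcing a [forcing_config()].
#' @param years total simulated years (default 30).
#' @param spinup_years initial years discarded from analyses (default 10).
#' @param closure_month `NULL` for year-round fishing, or 1-12 for a
#'   2.5-month fishing ban starting on day 15 of that month.
#' @param F_mult named numeric: fishing-mortality multiplier per species
#'   (default 1 for each).
#' @param init_biomass named numeric: initial biomass (t) per species
#'   (default the species' reference biomass).
#' @param init_buffer_batches initial adult reproductive buffer, in
#'   multiples of one egg batch (spin-up erases sensitivity).
#' @param forcing_table optional externally supplied forcing table (see
#'   [read_forcing_table()]); replaces the built-in climatology.
#' @param record_abundance record daily per-stage abundances (the most
#'   expensive output; calibration evaluations switch it off).
#' @param record_env record the daily mesozoo column mean (always on;
#'   kept for config completeness).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(species = list(anchovy = anchovy_params(),
                                      sardine = sardine_params()),
                       forcing = forcing_config(),
                       years = 30, spinup_years = 10,
                       closure_month = NULL,
                       F_mult = NULL,
                       init_biomass = NULL,
                       init_buffer_batches = 30,
                       forcing_table = NULL,
                       record_abundance = TRUE,
                       record_env = TRUE) {
  stopifnot(length(species) >= 1, years >= 1, spinup_years < years)
  if (is.null(names(species)))
    names(species) <- vapply(species, `[[`, "", "name")
  if (is.null(F_mult)) F_mult <- setNames(rep(1, length(species)),
                                          names(species))
  structure(list(species = species, forcing = forcing,
                 years = as.integer(years),
                 spinup_years = as.integer(spinup_years),
                 closure_month = closure_month,
                 F_mult = F_mult,
                 init_biomass = init_biomass,
                 init_buffer_batches = init_buffer_batches,
                 forcing_table = forcing_table,
                 record_abundance = record_abundance,
                 record_env = record_env),
            class = "sim_config")
}

# Seed the initial population: one SI per adult age class at the
# representative class length, abundances declining with total adult
# mortality and scaled to the requested initial biomass.
#' @keywords internal
init_population <- function(params, biomass_t = NULL,
                            buffer_batches = 30) {
  pop <- new_population(params)
  B <- (biomass_t %||% params$ref_biomass) * 1e6  # g
  nad <- params$n_adult_classes
  Wa <- weight_from_length(params$init_lengths, params)
  Z <- (params$M[5] + params$F_adult) * 365
  frac <- exp(-Z * (seq_len(nad) - 1))
  frac <- frac / sum(frac)
  for (a in seq_len(nad)) {
    si <- list(stage = 4L + a, N = B * frac[a] / Wa[a], W = Wa[a],
               L = params$init_lengths[a], age = a * 365 + 182,
               W_max_seen = Wa[a], veteran = TRUE,
               E_buffer = buffer_batches * params$E_egg * Wa[a])
    pop <- admit_si(pop, si, params)
  }
  pop
}

#' Run the coupled two-species simulation
#'
#' Executes the full daily loop for `config$years` years and returns the
#' daily time series, the per-season reproductive diagnostics and the
#' final state.  The simulation is fully deterministic.
#'
#' @param config a [sim_config()].
#' @param pops optional list of starting populations (e.g. the saved
#'   state of a previous run) keyed like `config$species`.
#' @param start_day starting day of year (default 1).
#' @return an object of class `sim_result`: list with
#'   \describe{
#'     \item{daily}{list of matrices `days x species`: `biomass` (t,
#'       juveniles+adults), `eggs`, `eggs_recruit`, `eggs_repeat`,
#'       `mean_W` (g, juveniles+adults), plus vectors `sst` and
#'       `meso_colmean`.}
#'     \item{seasons}{data.frame of per-SI spawning-season records:
#'       species, year, end day, age class, eggs released, capital index.}
#'     \item{pops}{final populations.}
#'     \item{bookkeeping}{zooplankton mass balance diagnostics (g wet):
#'       initial/final pool totals, cumulative relaxation production and
#'       grazing removal per pool.}
#'   }
#' @export
run_simulation <- function(config, pops = NULL, start_day = 1L) {
  cfg <- config$forcing
  clim <- if (!is.null(config$forcing_table))
    climate_from_table(config$forcing_table, cfg)
  else precompute_climate(cfg)
  spp <- config$species
  nsp <- length(spp)
  sp_names <- names(spp)
  ndays <- config$years * 365L

  if (is.null(pops))
    pops <- lapply(sp_names, function(s)
      init_population(spp[[s]],
                      (config$init_biomass %||% list())[[s]],
                      config$init_buffer_batches))
  names(pops) <- sp_names

  closed <- rep(FALSE, 365)
  if (!is.null(config$closure_month))
    closed[closure_days(config$closure_month)] <- TRUE
  tabs <- lapply(spp, species_tables, clim = clim, cfg = cfg)

  # dynamic zooplankton pools (profiles, mgC m^-3)
  micro <- clim$K_micro[, 365]
  meso <- clim$K_meso[, 365]
  surf <- clim$surf
  n_surf <- sum(surf)
  pool_to_wet <- cfg$bin_volume * cfg$mgc_to_wet
  relax_f <- exp(-cfg$relax_rate)
  p2d <- 1 / 1000 * cfg$carbon_to_wet  # mgC m^-3 -> g wet m^-3

  # recording
  M_biomass <- matrix(0, ndays, nsp, dimnames = list(NULL, sp_names))
  M_eggs <- M_eggs_rec <- M_eggs_rep <- M_meanW <- M_meanW_ad <- M_biomass
  V_sst <- V_meso <- numeric(ndays)
  rec_ab <- !isFALSE(config$record_abundance)
  M_abund <- if (rec_ab) lapply(spp, function(p)
    matrix(0, ndays, p$n_stages,
           dimnames = list(NULL, c("embryo", "early", "late", "juvenile",
                                   paste0("adult",
                                          seq_len(p$n_adult_classes))))))
  else NULL
  seas <- new.env(parent = emptyenv())
  seas$n <- 0L
  cap0 <- 4096L
  seas$species <- character(cap0); seas$year <- integer(cap0)
  seas$day <- integer(cap0); seas$age_class <- integer(cap0)
  seas$eggs <- numeric(cap0); seas$index <- numeric(cap0)
  seas$N <- numeric(cap0); seas$onset <- numeric(cap0)
  push_season <- function(sp, yr, day, cls, eggs, idx, N, onset) {
    n_new <- seas$n + length(cls)
    if (n_new > length(seas$year)) {
      grow <- function(x) c(x, x[seq_len(length(x))])
      for (f in c("species", "year", "day", "age_class", "eggs",
                  "index", "N", "onset")) seas[[f]] <- grow(seas[[f]])
    }
    r <- (seas$n + 1L):n_new
    seas$species[r] <- sp; seas$year[r] <- yr; seas$day[r] <- day
    seas$age_class[r] <- cls; seas$eggs[r] <- eggs
    seas$index[r] <- idx; seas$N[r] <- N; seas$onset[r] <- onset
    seas$n <- n_new
  }

  gate_prev <- setNames(rep(FALSE, nsp), sp_names)
  gate_day <- setNames(rep(NA_real_, nsp), sp_names)
  book <- list(
    init = c(micro = sum(micro), meso = sum(meso)) * pool_to_wet,
    production = c(micro = 0, meso = 0),
    removal = c(micro = 0, meso = 0))

  N_MIN <- 1e-3

  for (d in seq_len(ndays)) {
    doy <- ((start_day - 1L + d - 1L) %% 365L) + 1L
    yr <- ((d - 1L) %/% 365L) + 1L
    sst <- clim$sst[doy]
    Ts <- clim$T_surf[doy]; Td <- clim$T_deep[doy]
    lowfeed <- clim$lowfeed[doy]

    # --- environment: relaxation toward the day's carrying capacity
    if (cfg$grazing_feedback) {
      newm <- clim$K_micro[, doy] - (clim$K_micro[, doy] - micro) * relax_f
      book$production["micro"] <- book$production["micro"] +
        sum(newm - micro) * pool_to_wet
      micro <- newm
      newz <- clim$K_meso[, doy] - (clim$K_meso[, doy] - meso) * relax_f
      book$production["meso"] <- book$production["meso"] +
        sum(newz - meso) * pool_to_wet
      meso <- newz
    } else {
      micro <- clim$K_micro[, doy]
      meso <- clim$K_meso[, doy]
    }
    micro_s <- mean(micro[surf]) * p2d  # g wet m^-3 in the feeding layer
    # night-time meso field includes the ascended share of deep biomass
    meso_s <- (sum(meso[surf]) + cfg$night_ascent * sum(meso[!surf])) /
      n_surf * p2d

    # --- pass 1: desired consumption per species
    want <- vector("list", nsp)
    demand <- c(micro = 0, meso = 0)
    for (i in seq_len(nsp)) {
      p <- spp[[i]]; pop <- pops[[i]]
      f <- which(pop$stage >= 2L)
      if (!length(f)) { want[i] <- list(NULL); next }
      s <- pop$stage[f]; W <- pop$W[f]
      cmax <- p$a_c * W^p$b_c * tabs[[i]]$fc[, doy][s]
      r1 <- micro_s * p$v_micro[s] / p$k_micro[s]
      r2 <- meso_s * p$v_meso[s] / p$k_meso[s]
      den <- 1 + r1 + r2
      ci <- cmax * r1 / den
      cz <- cmax * r2 / den
      NW <- pop$N[f] * W
      demand["micro"] <- demand["micro"] + sum(ci * NW)
      demand["meso"] <- demand["meso"] + sum(cz * NW)
      want[[i]] <- list(f = f, s = s, W = W, ci = ci, cz = cz)
    }

    # --- grazing: cap at exposed biomass, remove exposure-weighted
    alpha <- c(micro = 1, meso = 1)
    if (cfg$grazing_feedback) {
      w_me <- ifelse(surf, 1, cfg$night_ascent)
      avail_mi <- sum(micro[surf]) * pool_to_wet
      avail_me <- sum(meso * w_me) * pool_to_wet
      rem_mi <- min(demand["micro"], avail_mi)
      rem_me <- min(demand["meso"], avail_me)
      if (demand["micro"] > 0) alpha["micro"] <- rem_mi / demand["micro"]
      if (demand["meso"] > 0) alpha["meso"] <- rem_me / demand["meso"]
      if (avail_mi > 0) micro[surf] <- micro[surf] * (1 - rem_mi / avail_mi)
      if (avail_me > 0) meso <- meso * (1 - (rem_me / avail_me) * w_me)
      book$removal["micro"] <- book$removal["micro"] + rem_mi
      book$removal["meso"] <- book$removal["meso"] + rem_me
    }

    # --- pass 2: budgets, allocation, spawning, mortality, transitions
    for (i in seq_len(nsp)) {
      p <- spp[[i]]; pop <- pops[[i]]; sp <- sp_names[i]
      Fday <- if (closed[doy]) 0 else p$F_adult * config$F_mult[[sp]]

      # embryos: temperature-driven development only
      e <- which(pop$stage == 1L)
      if (length(e))
        pop$dev[e] <- pop$dev[e] + 1 / p$embryo_dur(Ts)

      w <- want[[i]]
      if (!is.null(w)) {
        f <- w$f; s <- w$s; W <- w$W
        C_mi <- w$ci * alpha[["micro"]]
        C_me <- w$cz * alpha[["meso"]]
        C <- C_mi + C_me
        rp <- p$resp
        U <- tabs[[i]]$aA[, doy][s] * W^p$b_A_stage[s]
        R <- rp$a_r * W^rp$b_r * tabs[[i]]$q10[, doy][s] * exp(rp$d_r * U)
        EG <- p$a_f_stage[s] * C
        A <- C - (R + EG + p$a_sda * (C - EG) +
                  p$a_e * (C - EG) + p$b_e)

        # energy allocation (growth / buffer / emergency maintenance)
        st_sub <- list(E_buffer = pop$E_buffer[f], ar_cum = pop$ar_cum[f])
        al <- allocate_energy(A, W, pop$L[f], st_sub, p)
        pop$E_buffer[f] <- al$state$E_buffer
        pop$ar_cum[f] <- al$state$ar_cum
        # a hunger day is one the buffer could not bridge (soma shrinks)
        soma_deficit <- al$growth < 0
        W_new <- W * (1 + al$growth * p$cal_ratio)
        W_new <- pmax(W_new, 1e-9)
        pop$W[f] <- W_new
        pop$L[f] <- pmax(pop$L[f], length_from_weight(W_new, p))
        # reference weight for the starvation rule: rolling maximum that
        # relaxes toward current weight (~90 d), so the 35% criterion
        # measures acute loss, not lifetime loss over seasonal cycles
        wm <- pop$W_max_seen[f]
        pop$W_max_seen[f] <- pmax(W_new, wm - (wm - W_new) / 90)

        # hunger / atresia (adult reproductive bookkeeping)
        ad <- f[s >= 5L]
        if (length(ad)) {
          deficit <- soma_deficit[s >= 5L]
          open_before <- pop$season_open[ad]
          hs <- list(hunger_days = pop$hunger_days[ad],
                     season_open = pop$season_open[ad],
                     egg_cum = pop$egg_cum[ad])
          hs <- update_hunger(hs, deficit, p)
          pop$hunger_days[ad] <- hs$hunger_days
          pop$season_open[ad] <- hs$season_open
          closed_now <- open_before & !hs$season_open
          rec <- ad[closed_now & pop$egg_cum[ad] > 0]
          if (length(rec)) {
            push_season(sp, yr, doy,
                        pmin(pmax(floor(pop$age[rec] / 365), 1),
                             p$n_adult_classes),
                        pop$egg_cum[rec],
                        capital_index(pop$buf_start[rec],
                                      pop$E_buffer[rec],
                                      pop$ar_cum[rec], pop$egg_cum[rec]),
                        pop$N[rec],
                        pop$first_spawn[rec] - pop$season_t0[rec])
            pop$veteran[rec] <- TRUE
          }
        }

        # starvation rule (35% cumulative weight loss)
        starved <- f[!starvation_check(pop$W[f], pop$W_max_seen[f])]
        if (length(starved)) {
          pop$stage[starved] <- 0L
          pop$N[starved] <- 0
        }
      }

      # --- season edges driven by the SST gate
      gate <- sst_gate_open(sst, p)
      adult <- which(pop$stage >= 5L)
      if (gate && !gate_prev[[sp]]) {
        rs <- list(E_buffer = pop$E_buffer, hunger_days = pop$hunger_days,
                   season_open = pop$season_open,
                   buf_start = pop$buf_start, ar_cum = pop$ar_cum,
                   egg_cum = pop$egg_cum)
        rs <- season_start(rs, adult)
        for (fld in names(rs)) pop[[fld]] <- rs[[fld]]
        pop$season_t0[adult] <- d
        pop$first_spawn[adult] <- NA_real_
        gate_day[[sp]] <- d
      } else if (!gate && gate_prev[[sp]]) {
        rec <- adult[pop$egg_cum[adult] > 0 & pop$season_open[adult]]
        if (length(rec)) {
          push_season(sp, yr, doy,
                      pmin(pmax(floor(pop$age[rec] / 365), 1),
                           p$n_adult_classes),
                      pop$egg_cum[rec],
                      capital_index(pop$buf_start[rec], pop$E_buffer[rec],
                                    pop$ar_cum[rec], pop$egg_cum[rec]),
                      pop$N[rec],
                      pop$first_spawn[rec] - pop$season_t0[rec])
          pop$veteran[rec] <- TRUE
        }
        pop$season_open[adult] <- FALSE
      }
      gate_prev[[sp]] <- gate

      # --- spawning
      if (length(adult) && gate) {
        rs <- list(E_buffer = pop$E_buffer[adult],
                   season_open = pop$season_open[adult])
        sp_mask <- sst_gate_open(sst, p) &
          pop$L[adult] > p$L_m &
          rs$E_buffer >= p$E_egg * pop$W[adult] &
          rs$season_open
        if (any(sp_mask)) {
          sel <- adult[sp_mask]
          fs_na <- sel[is.na(pop$first_spawn[sel])]
          if (length(fs_na)) pop$first_spawn[fs_na] <- d
          debit <- p$E_egg * pop$W[sel]
          pop$E_buffer[sel] <- pop$E_buffer[sel] - debit
          pop$egg_cum[sel] <- pop$egg_cum[sel] + debit
          eggs_si <- p$DSF * pop$W[sel] * pop$N[sel]
          eggs_tot <- sum(eggs_si)
          recruit <- !pop$veteran[sel]  # first-season spawners
          M_eggs[d, i] <- eggs_tot
          M_eggs_rec[d, i] <- sum(eggs_si[recruit])
          M_eggs_rep[d, i] <- eggs_tot - M_eggs_rec[d, i]
          if (eggs_tot > 0) {
            Wh <- weight_from_length(p$length_windows[1], p)
            pop <- admit_si(pop, list(stage = 1L, N = eggs_tot, W = Wh,
                                      L = p$length_windows[1], age = 0,
                                      dev = 0), p)
          }
        }
      }

      # --- mortality
      al <- which(pop$stage > 0L)
      if (length(al)) {
        s <- pop$stage[al]
        Fv <- ifelse(s >= 5L, Fday, 0)
        pop$N[al] <- pop$N[al] * exp(-(p$M_stage[s] + Fv))
        tiny <- al[pop$N[al] < N_MIN]
        if (length(tiny)) { pop$stage[tiny] <- 0L; pop$N[tiny] <- 0 }
      }

      # --- hatching and stage transitions
      h <- which(pop$stage == 1L & pop$dev >= 1)
      if (length(h)) {
        Lh <- p$length_windows[1]
        pop$stage[h] <- 2L
        pop$L[h] <- Lh
        pop$W[h] <- weight_from_length(Lh, p)
        pop$W_max_seen[h] <- pop$W[h]
        pop$dev[h] <- 0
      }
      tr <- stage_transition(pop, p)
      pop <- tr$pop
      na <- tr$newly_adult[pop$stage[tr$newly_adult] >= 5L]
      if (length(na) && gate_prev[[sp]]) {
        rs <- list(E_buffer = pop$E_buffer, hunger_days = pop$hunger_days,
                   season_open = pop$season_open,
                   buf_start = pop$buf_start, ar_cum = pop$ar_cum,
                   egg_cum = pop$egg_cum)
        rs <- season_start(rs, na)
        for (fld in names(rs)) pop[[fld]] <- rs[[fld]]
        # onset is measured from the population's season opening, so
        # mid-season maturers carry the gate-opening day as reference
        pop$season_t0[na] <- gate_day[[sp]] %||% d
        pop$first_spawn[na] <- NA_real_
      }
      al <- which(pop$stage > 0L)
      pop$age[al] <- pop$age[al] + 1

      # --- daily records
      if (rec_ab && length(al))
        M_abund[[i]][d, ] <- unname(rowsum(
          c(pop$N[al], numeric(spp[[i]]$n_stages)),
          c(pop$stage[al], seq_len(spp[[i]]$n_stages))))[, 1]
      ex <- al[pop$stage[al] >= 4L]
      M_biomass[d, i] <- sum(pop$N[ex] * pop$W[ex]) / 1e6
      M_meanW[d, i] <- if (length(ex) && sum(pop$N[ex]) > 0)
        sum(pop$N[ex] * pop$W[ex]) / sum(pop$N[ex]) else NA_real_
      ad_ex <- al[pop$stage[al] >= 5L]
      M_meanW_ad[d, i] <- if (length(ad_ex) && sum(pop$N[ad_ex]) > 0)
        sum(pop$N[ad_ex] * pop$W[ad_ex]) / sum(pop$N[ad_ex]) else NA_real_
      pops[[i]] <- pop
    }
    V_sst[d] <- sst
    V_meso[d] <- mean(meso)
  }

  book$final <- c(micro = sum(micro), meso = sum(meso)) * pool_to_wet
  r <- seq_len(seas$n)
  seasons <- data.frame(species = seas$species[r], year = seas$year[r],
                        day = seas$day[r], age_class = seas$age_class[r],
                        eggs_energy = seas$eggs[r],
                        capital_index = seas$index[r], N = seas$N[r],
                        onset = seas$onset[r],
                        stringsAsFactors = FALSE)
  structure(list(config = config,
                 daily = list(biomass = M_biomass, eggs = M_eggs,
                              eggs_recruit = M_eggs_rec,
                              eggs_repeat = M_eggs_rep, mean_W = M_meanW,
                              mean_W_adult = M_meanW_ad,
                              sst = V_sst, meso_colmean = V_meso,
                              abundance = M_abund),
                 seasons = seasons,
                 pops = pops,
                 bookkeeping = book),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  yrs <- x$config$years; sp <- colnames(x$daily$biomass)
  cat(sprintf("<sim_result: %d years, species %s>\n", yrs,
              paste(sp, collapse = ", ")))
  for (s in sp)
    cat(sprintf("  %s mean post-spin-up biomass: %.0f t\n", s,
                mean_biomass(x, s)))
  invisible(x)
}

#' Mean post-spin-up biomass
#'
#' @param sim a `sim_result`.
#' @param species species name.
#' @param years range of simulation years to average (default from the
#'   end of spin-up to the last year).
#' @return mean biomass in tonnes.
#' @export
mean_biomass <- function(sim, species, years = NULL) {
  if (is.null(years))
    years <- c(sim$config$spinup_years + 1L, sim$config$years)
  d0 <- (years[1] - 1L) * 365L + 1L
  d1 <- years[2] * 365L
  mean(sim$daily$biomass[d0:d1, species])
}

#' Abundance-weighted mean capital index per species and age class
#'
#' Averages the per-season capital indices recorded by the simulator over
#' the requested simulation years, weighting each super-individual season
#' record by its abundance.
#'
#' @param sim a `sim_result`.
#' @param years range of simulation years (default post-spin-up).
#' @return data.frame with `species`, `age_class`, `capital_index`, `n`
#'   (number of SI-season records).
#' @export
capital_index_summary <- function(sim, years = NULL) {
  if (is.null(years))
    years <- c(sim$config$spinup_years + 1L, sim$config$years)
  s <- sim$seasons
  s <- s[s$year >= years[1] & s$year <= years[2] &
           is.finite(s$capital_index), ]
  if (!nrow(s))
    return(data.frame(species = character(), age_class = integer(),
                      capital_index = numeric(), n = integer()))
  agg <- do.call(rbind, lapply(split(s, list(s$species, s$age_class),
                                     drop = TRUE), function(g)
    data.frame(species = g$species[1], age_class = g$age_class[1],
               capital_index = sum(g$capital_index * g$N) / sum(g$N),
               n = nrow(g))))
  rownames(agg) <- NULL
  agg[order(agg$species, agg$age_class), ]
}

#' Days of year with population egg release
#'
#' @param sim a `sim_result`.
#' @param species species name.
#' @param years range of simulation years (default post-spin-up).
#' @param which `"all"`, `"recruit"` (age-1 spawners) or `"repeat"`.
#' @return sorted unique days of year on which eggs were released.
#' @export
spawning_days <- function(sim, species, years = NULL,
                          which = c("all", "recruit", "repeat")) {
  which <- match.arg(which)
  if (is.null(years))
    years <- c(sim$config$spinup_years + 1L, sim$config$years)
  mat <- switch(which, all = sim$daily$eggs,
                recruit = sim$daily$eggs_recruit,
                "repeat" = sim$daily$eggs_repeat)
  d0 <- (years[1] - 1L) * 365L + 1L
  d1 <- min(years[2] * 365L, nrow(mat))
  dd <- d0:d1
  act <- dd[mat[dd, species] > 0]
  sort(unique(((act - 1L) %% 365L) + 1L))
}

#' Spawning-onset summary by recruit/repeat group
#'
#' Abundance-weighted mean of the per-season first-spawning delay (days
#' from the season's opening to an SI's first egg release), split into
#' age-1 spawners and age-2+ spawners, from the simulator's season log.
#'
#' @param sim a `sim_result`.
#' @param species species name.
#' @param years range of simulation years (default post-spin-up).
#' @return named numeric: `age1` and `age2plus` mean onset delay (days).
#' @export
spawning_onsets <- function(sim, species, years = NULL) {
  if (is.null(years))
    years <- c(sim$config$spinup_years + 1L, sim$config$years)
  s <- sim$seasons
  s <- s[s$species == species & s$year >= years[1] & s$year <= years[2] &
           is.finite(s$onset), ]
  grp <- ifelse(s$age_class <= 1, "age1", "age2plus")
  out <- vapply(c("age1", "age2plus"), function(g) {
    sel <- grp == g
    if (!any(sel)) return(NA_real_)
    sum(s$onset[sel] * s$N[sel]) / sum(s$N[sel])
  }, 0)
  out
}

#' Single super-individual growth trajectory
#'
#' Simulates one individual's growth under the pure climatology (no
#' grazing feedback, no mortality, no spawning debits), the harness used
#' by the genetic-algorithm calibration: energy allocation still routes
#' `(1-k)` of surplus to the buffer once mature, so post-maturity growth
#' reflects the allocation split.
#'
#' @param params a [species_params()] object (its `k_half` are the
#'   parameters under calibration).
#' @param clim tables from [precompute_climate()].
#' @param hatch_doy day of year of hatching (start of the early-larva
#'   stage).
#' @param n_days days to simulate.
#' @param cfg the [forcing_config()] used to build `clim`.
#' @param state optional saved state to continue from (as returned in
#'   `$state`).
#' @return list with `W`, `L`, `stage` (per-day vectors, day 1 = first
#'   simulated day) and `state` (for continuation).
#' @export
simulate_si <- function(params, clim, hatch_doy = 152L, n_days = 365L,
                        cfg = forcing_config(), state = NULL) {
  p <- params
  p2d <- cfg$carbon_to_wet / 1000
  if (is.null(state)) {
    L <- p$length_windows[1]
    state <- list(W = weight_from_length(L, p), L = L, age = 0,
                  stage = 2L, doy = as.integer(hatch_doy), buf = 0)
  }
  W <- state$W; L <- state$L; age <- state$age
  stage <- state$stage; doy <- state$doy; buf <- state$buf
  win <- p$length_windows
  outW <- outL <- numeric(n_days); outS <- integer(n_days)
  rp <- p$resp
  # hoisted constants (this loop is the genetic algorithm's inner kernel)
  T_surf <- clim$T_surf; T_deep <- clim$T_deep
  micro_v <- clim$micro_surf * p2d; meso_v <- clim$meso_night * p2d
  lowfeed_v <- clim$lowfeed
  day_frac <- cfg$day_fraction; night_frac <- 1 - cfg$day_fraction
  a_c <- p$a_c; b_c <- p$b_c; T_max <- p$T_max
  # per-stage Thornton-Lesem constants of the temperature scalar
  span_s <- T_max - p$T_opt_stage
  S_s <- log(p$Q_c_stage) * span_s
  Y_s <- log(p$Q_c_stage) * (span_s + 2)
  X_s <- S_s^2 * (1 + sqrt(1 + 40 / Y_s))^2 / 400
  v1 <- p$v_micro; k1 <- p$k_micro; v2 <- p$v_meso; k2 <- p$k_meso
  aA_st <- p$a_A_stage; bA_st <- p$b_A_stage; fidx <- p$fidx
  aA_lf <- rp$a_A_lowfeed; aA_cold <- rp$a_A_cold
  cA_warm <- rp$c_A_warm; cA_cold <- rp$c_A_cold
  a_r <- rp$a_r; b_r <- rp$b_r; Q10 <- rp$Q10; T_m <- rp$T_m
  d_r <- rp$d_r
  aF_st <- p$a_f_stage; a_sda <- p$a_sda; a_e <- p$a_e; b_e <- p$b_e
  L_m <- p$L_m; k_alloc <- p$k_alloc; cal_ratio <- p$cal_ratio
  nad <- p$n_adult_classes
  # piecewise length-weight inverse constants
  lw <- p$lw
  lb0 <- lw[["b0"]]; ld1 <- lw[["d1"]]; ld2 <- lw[["d2"]]
  ls1 <- lw[["b1"]]; ls2 <- lw[["b1"]] + lw[["b2"]]
  ls3 <- ls2 + lw[["b3"]]
  ly1 <- lb0 + lw[["b1"]] * ld1; ly2 <- ly1 + ls2 * (ld2 - ld1)
  for (t in seq_len(n_days)) {
    Ts <- T_surf[doy]; Td <- T_deep[doy]
    if (Ts >= T_max) fc <- 0
    else {
      X <- X_s[stage]
      V <- (T_max - Ts) / span_s[stage]
      fc <- V^X * exp(X * (1 - V))
      fc <- min(max(fc, 0), 1)
    }
    cmax <- a_c * W^b_c * fc
    r1 <- micro_v[doy] * v1[stage] / k1[stage]
    r2 <- meso_v[doy] * v2[stage] / k2[stage]
    C <- cmax * (r1 + r2) / (1 + r1 + r2)
    T_resp <- if (stage >= 3L) day_frac * Td + night_frac * Ts else Ts
    warm <- T_resp >= 12
    a_A <- if (warm) {
      if (lowfeed_v[doy] && fidx[stage] == 3L) aA_lf else aA_st[stage]
    } else aA_cold
    c_A <- if (warm) cA_warm else cA_cold
    U <- a_A * W^bA_st[stage] * exp(c_A * T_resp)
    R <- a_r * W^b_r * Q10^((T_resp - T_m) / 10) * exp(d_r * U)
    EG <- aF_st[stage] * C
    A <- C - (R + EG + a_sda * (C - EG) + a_e * (C - EG) + b_e)
    if (A >= 0 && L >= L_m) {
      g <- k_alloc * A
      buf <- buf + (1 - k_alloc) * A * W
    } else if (A >= 0) {
      g <- A
    } else {
      need <- -A * W
      draw <- min(buf, need)
      buf <- buf - draw
      g <- -(need - draw) / W
    }
    W <- max(W * (1 + g * cal_ratio), 1e-9)
    y <- log10(W)
    x <- if (y <= ly1) (y - lb0) / ls1
      else if (y <= ly2) ld1 + (y - ly1) / ls2
      else ld2 + (y - ly2) / ls3
    L <- max(L, 10^x)
    age <- age + 1
    if (stage == 2L && L >= win[2]) stage <- 3L
    if (stage == 3L && L >= win[3]) stage <- 4L
    if (stage == 4L && L >= L_m)
      stage <- 4L + min(max(floor(age / 365), 1), nad)
    if (stage >= 5L)
      stage <- 4L + min(max(floor(age / 365), 1), nad)
    outW[t] <- W; outL[t] <- L; outS[t] <- stage
    doy <- if (doy == 365L) 1L else doy + 1L
  }
  list(W = outW, L = outL, stage = outS,
       state = list(W = W, L = L, age = age, stage = stage, doy = doy,
                    buf = buf))
}
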