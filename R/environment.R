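# Synthetic water-column forcing: a parametric climatology of temperature
# and micro/mesozooplankton for a 0-100 m shelf column, with linear
# relaxation of the plankton pools toward their day-of-year carrying
# capacity and a grazing sink applied by the fish.  This stands in for the
# hydrodynamic/biogeochemical model that a coupled application would use;
# only the emergent seasonal patterns are represented: winter mixing,
# summer thermal stratification with a deep mesozooplankton maximum, and a
# mesozooplankton seasonal cycle rising from mid-December to an early
# summer peak then dropping sharply to a low autumn plateau.

#' Forcing configuration for the synthetic climatology
#'
#' Parameters of the built-in seasonal water-column climatology.  With the
#' default values, SST crosses 15 C upward in mid-April and 16 C downward
#' in mid-November (so the anchovy and sardine SST spawning gates open in
#' late April and November respectively), and the column-mean
#' mesozooplankton concentration peaks in mid-June and stays low from
#' August to mid-December.
#'
#' @param sst_anchors mid-month SST values (C), January to December,
#'   interpolated periodically.
#' @param T_deep deep-water temperature (C), near-constant year-round.
#' @param z_thermo,thermo_width summer thermocline depth and transition
#'   width (m).
#' @param meso_low,meso_peak autumn minimum and early-summer maximum of
#'   column-mean mesozooplankton (mgC m^-3).
#' @param meso_rise_start,meso_peak_day,meso_crash_end day-of-year anchors
#'   of the mesozooplankton cycle (rise begins mid-December, peaks in
#'   June, sharp decline complete by mid-August).
#' @param micro_low,micro_peak,micro_rise_start,micro_peak_day,micro_crash_end
#'   same for microzooplankton (earlier, flatter spring cycle).
#' @param deep_max_depth,deep_max_width centre and width (m) of the
#'   Gaussian deep mesozooplankton maximum during stratification.
#' @param surface_scale,micro_surface_scale e-folding depth (m) of the
#'   surface-concentrated profiles.
#' @param night_ascent fraction of sub-thermocline mesozooplankton that
#'   migrates into the surface layer at night (nocturnal ascent), where
#'   the fish feed; the night-time prey field of the 0-30 m layer
#'   therefore includes part of the deep-maximum biomass.
#' @param relax_rate relaxation rate of the plankton pools toward the
#'   climatology (d^-1).
#' @param grazing_feedback logical; if `FALSE` the pools follow the pure
#'   climatology and fish grazing does not deplete them.
#' @param habitat_area horizontal area represented by the column (m^2);
#'   converts between population consumption (g) and concentration
#'   (mgC m^-3).
#' @param carbon_to_wet wet mass : carbon mass ratio of zooplankton
#'   (g wet per g C).
#' @param n_bins,max_depth vertical grid: `n_bins` equal bins over
#'   0..`max_depth` m.
#' @param day_fraction fraction of the day spent in the daytime (deep)
#'   layer by vertically migrating stages, used to weight respiration
#'   temperature.
#' @param lowfeed_frac juveniles switch to the low-feeding-activity
#'   swimming intercept when column-mean mesozooplankton falls below this
#'   fraction of its annual peak.
#' @return an object of class `forcing_config`.
#' @export
forcing_config <- function(sst_anchors = c(13.8, 13.2, 13.8, 15.0, 18.5,
                                           22.5, 25.0, 25.5, 23.5, 19.5,
                                           15.8, 14.3),
                           T_deep = 14.5,
                           z_thermo = 30, thermo_width = 4,
                           meso_low = 8, meso_peak = 45,
                           meso_rise_start = 350, meso_peak_day = 165,
                           meso_crash_end = 230,
                           micro_low = 18, micro_peak = 35,
                           micro_rise_start = 330, micro_peak_day = 130,
                           micro_crash_end = 250,
                           deep_max_depth = 40, deep_max_width = 15,
                           surface_scale = 40, micro_surface_scale = 30,
                           night_ascent = 0.15,
                           relax_rate = 0.1,
                           grazing_feedback = TRUE,
                           habitat_area = 5e10,
                           carbon_to_wet = 12.5,
                           n_bins = 10L, max_depth = 100,
                           day_fraction = 0.5,
                           lowfeed_frac = 0.5) {
  stopifnot(length(sst_anchors) == 12, all(is.finite(sst_anchors)),
            meso_low > 0, meso_peak > meso_low,
            micro_low > 0, micro_peak > micro_low,
            night_ascent >= 0, night_ascent <= 1,
            relax_rate > 0, habitat_area > 0, carbon_to_wet > 0,
            n_bins >= 2, max_depth > 0,
            day_fraction >= 0, day_fraction <= 1)
  cfg <- list(sst_anchors = sst_anchors,
              anchor_days = c(15, 46, 74, 105, 135, 166, 196, 227,
                              258, 288, 319, 349),
              T_deep = T_deep, z_thermo = z_thermo,
              thermo_width = thermo_width,
              meso_low = meso_low, meso_peak = meso_peak,
              meso_rise_start = meso_rise_start,
              meso_peak_day = meso_peak_day,
              meso_crash_end = meso_crash_end,
              micro_low = micro_low, micro_peak = micro_peak,
              micro_rise_start = micro_rise_start,
              micro_peak_day = micro_peak_day,
              micro_crash_end = micro_crash_end,
              deep_max_depth = deep_max_depth,
              deep_max_width = deep_max_width,
              surface_scale = surface_scale,
              micro_surface_scale = micro_surface_scale,
              night_ascent = night_ascent,
              relax_rate = relax_rate,
              grazing_feedback = grazing_feedback,
              habitat_area = habitat_area,
              carbon_to_wet = carbon_to_wet,
              n_bins = as.integer(n_bins), max_depth = max_depth,
              dz = max_depth / n_bins,
              depth = (seq_len(n_bins) - 0.5) * (max_depth / n_bins),
              day_fraction = day_fraction,
              lowfeed_frac = lowfeed_frac)
  # g wet mass of one pool unit: conc (mgC m^-3) * bin volume * mgC->g wet
  cfg$mgc_to_wet <- carbon_to_wet / 1000
  cfg$bin_volume <- cfg$dz * habitat_area
  structure(cfg, class = "forcing_config")
}

#' @keywords internal
wrap_doy <- function(day_of_year) {
  if (any(!is.finite(day_of_year)) || any(day_of_year < 1))
    stop("day_of_year must be >= 1")
  ((day_of_year - 1) %% 365) + 1
}

#' Climatological sea-surface temperature
#'
#' Periodic linear interpolation of the mid-month SST anchors.
#'
#' @param day_of_year day of the (365-day) year; values beyond 365 wrap.
#' @param cfg a [forcing_config()].
#' @return SST in degrees C (vectorised).
#' @export
seasonal_sst <- function(day_of_year, cfg = forcing_config()) {
  d <- wrap_doy(day_of_year)
  days <- c(cfg$anchor_days[12] - 365, cfg$anchor_days,
            cfg$anchor_days[1] + 365)
  vals <- c(cfg$sst_anchors[12], cfg$sst_anchors, cfg$sst_anchors[1])
  stats::approx(days, vals, xout = d)$y
}

# Seasonal cycle: low plateau, steady (linear) rise from `rise_start`
# (wrapping year end) to a peak at `peak_day`, sharp cosine crash back
# to the low by `crash_end`.
#' @keywords internal
seasonal_cycle <- function(day_of_year, low, peak, rise_start, peak_day,
                           crash_end) {
  d <- wrap_doy(day_of_year)
  # unwrap so that rise_start <= peak_day < crash_end on a linear axis
  rise_len <- (peak_day - rise_start) %% 365
  crash_len <- (crash_end - peak_day) %% 365
  dd <- (d - rise_start) %% 365  # days since rise start
  amp <- peak - low
  val <- ifelse(dd <= rise_len,
                low + amp * dd / rise_len,
         ifelse(dd <= rise_len + crash_len,
                low + amp * (1 + cos(pi * (dd - rise_len) / crash_len)) / 2,
                low))
  val
}

#' Column-mean zooplankton climatology
#'
#' @param day_of_year day of year (vectorised, wraps beyond 365).
#' @param cfg a [forcing_config()].
#' @param pool `"meso"` or `"micro"`.
#' @return column-mean concentration, mgC m^-3.
#' @export
seasonal_colmean <- function(day_of_year, cfg = forcing_config(),
                             pool = c("meso", "micro")) {
  pool <- match.arg(pool)
  if (pool == "meso")
    seasonal_cycle(day_of_year, cfg$meso_low, cfg$meso_peak,
                   cfg$meso_rise_start, cfg$meso_peak_day,
                   cfg$meso_crash_end)
  else
    seasonal_cycle(day_of_year, cfg$micro_low, cfg$micro_peak,
                   cfg$micro_rise_start, cfg$micro_peak_day,
                   cfg$micro_crash_end)
}

#' Water-column state for one day of the climatology
#'
#' Builds the full depth-resolved environment state for a given day of
#' year: temperature profile (mixed in winter, stratified in summer with a
#' thermocline at `cfg$z_thermo`), and micro/mesozooplankton profiles whose
#' column means follow the seasonal cycles.  During stratification the
#' mesozooplankton profile develops a Gaussian deep maximum below the
#' thermocline; in the mixed season it is surface-concentrated.
#'
#' Deterministic in `(day_of_year, cfg)` and periodic with period 365.
#'
#' @param day_of_year day of year (>= 1; wraps beyond 365).
#' @param cfg a [forcing_config()].
#' @return an object of class `environment_state`: list with `day_of_year`,
#'   `depth` (bin centres, m), `dz`, `temperature`, `microzoo`, `mesozoo`
#'   (mgC m^-3 per bin) and `sst`.
#' @export
seasonal_forcing <- function(day_of_year, cfg = forcing_config()) {
  stopifnot(length(day_of_year) == 1)
  d <- wrap_doy(day_of_year)
  z <- cfg$depth
  sst <- seasonal_sst(d, cfg)
  wz <- 1 / (1 + exp((z - cfg$z_thermo) / cfg$thermo_width))
  temp <- cfg$T_deep + (sst - cfg$T_deep) * wz
  # stratification index in [0, 1]
  s <- min(1, max(0, (sst - cfg$T_deep - 1) / 4))

  meso_shape <- (1 - s) * exp(-z / cfg$surface_scale) +
    s * exp(-(z - cfg$deep_max_depth)^2 / (2 * cfg$deep_max_width^2))
  meso_shape <- meso_shape / mean(meso_shape)
  micro_shape <- exp(-z / cfg$micro_surface_scale)
  micro_shape <- micro_shape / mean(micro_shape)

  st <- list(day_of_year = d, depth = z, dz = cfg$dz,
             temperature = temp,
             microzoo = seasonal_colmean(d, cfg, "micro") * micro_shape,
             mesozoo = seasonal_colmean(d, cfg, "meso") * meso_shape,
             sst = temp[1])
  structure(st, class = "environment_state")
}

#' @export
print.environment_state <- function(x, ...) {
  cat(sprintf("<environment_state day %d: SST %.2f C, meso %.1f, micro %.1f mgC m-3 (column mean)>\n",
              x$day_of_year, x$sst, mean(x$mesozoo), mean(x$microzoo)))
  invisible(x)
}

#' Column-mean concentration of an environment state
#'
#' @param state an `environment_state`.
#' @param pool `"meso"` or `"micro"`.
#' @return column mean in mgC m^-3.
#' @export
column_mean <- function(state, pool = c("meso", "micro")) {
  pool <- match.arg(pool)
  mean(if (pool == "meso") state$mesozoo else state$microzoo)
}

#' Night-time exposure weight per depth bin
#'
#' Microzooplankton is grazed in the surface layer only; for
#' mesozooplankton a fraction `night_ascent` of the sub-thermocline
#' biomass ascends into the surface layer at night, so deep bins are
#' partially exposed to the nocturnally feeding fish.
#' @keywords internal
exposure_weights <- function(state, cfg, pool) {
  surf <- state$depth <= cfg$z_thermo
  if (pool == "meso") ifelse(surf, 1, cfg$night_ascent)
  else ifelse(surf, 1, 0)
}

#' Wet mass of a zooplankton pool exposed to night-time feeding
#' @keywords internal
exposed_pool_wet <- function(state, cfg, pool) {
  conc <- if (pool == "meso") state$mesozoo else state$microzoo
  sum(conc * exposure_weights(state, cfg, pool)) * cfg$bin_volume *
    cfg$mgc_to_wet
}

#' Remove grazed zooplankton from the water column
#'
#' Applies the fish consumption demand to the night-time prey pools:
#' fish feed in the surface layer (0 to `z_thermo` m), where the full
#' surface biomass and, for mesozooplankton, a fraction `night_ascent`
#' of the sub-thermocline biomass are exposed.  Each pool is reduced by
#' at most its exposed biomass, proportionally to each bin's exposed
#' mass; the realised removal is reported back so that the fish model
#' can cap realised consumption at prey availability.
#'
#' @param state an `environment_state`.
#' @param demand list with elements `micro` and `meso`: total demand in
#'   g wet mass over the habitat, both >= 0.
#' @param cfg the [forcing_config()].
#' @param dt time step in days (demand is already integrated over `dt`).
#' @return list with `state` (updated), `removed` (g wet per pool) and
#'   `frac` (realised / demanded, 1 when the pool suffices).
#' @export
graze <- function(state, demand, cfg = forcing_config(), dt = 1) {
  demand <- list(micro = demand$micro %||% 0, meso = demand$meso %||% 0)
  if (any(unlist(demand) < 0)) stop("grazing demand must be non-negative")
  out <- list(micro = 0, meso = 0)
  frac <- list(micro = 1, meso = 1)
  for (pool in c("micro", "meso")) {
    dem <- demand[[pool]]
    if (dem <= 0) next
    w <- exposure_weights(state, cfg, pool)
    field <- if (pool == "meso") "mesozoo" else "microzoo"
    mass <- state[[field]] * cfg$bin_volume * cfg$mgc_to_wet  # per bin
    exposed <- sum(mass * w)
    rem <- min(dem, exposed)
    if (exposed > 0)
      state[[field]] <- state[[field]] * (1 - (rem / exposed) * w)
    out[[pool]] <- rem
    frac[[pool]] <- rem / dem
  }
  list(state = state, removed = out, frac = frac)
}

#' Relax zooplankton pools toward the day-of-year climatology
#'
#' Linear relaxation `dP/dt = r (K - P)` integrated exactly over `dt`:
#' `P(t+dt) = K - (K - P) exp(-r dt)`.  This is the regrowth term of the
#' two-way coupling; without grazing the pools converge to the seasonal
#' climatology.  The temperature profile is prescribed (reset to the
#' climatology each call).
#'
#' @param state an `environment_state`.
#' @param cfg the [forcing_config()].
#' @param dt time step in days (> 0).
#' @return list with `state` (updated, `day_of_year` advanced by `dt`) and
#'   `production` (net g wet mass added to each pool by relaxation).
#' @export
relax_to_climatology <- function(state, cfg = forcing_config(), dt = 1) {
  stopifnot(dt > 0)
  doy <- wrap_doy(state$day_of_year + dt)
  clim <- seasonal_forcing(doy, cfg)
  f <- exp(-cfg$relax_rate * dt)
  prod <- list(micro = 0, meso = 0)
  for (pool in c("micro", "meso")) {
    field <- if (pool == "meso") "mesozoo" else "microzoo"
    old <- state[[field]]
    new <- clim[[field]] - (clim[[field]] - old) * f
    prod[[pool]] <- sum(new - old) * cfg$bin_volume * cfg$mgc_to_wet
    state[[field]] <- new
  }
  state$day_of_year <- doy
  state$temperature <- clim$temperature
  state$sst <- clim$sst
  list(state = state, production = prod)
}

#' Day/night layer summary of an environment state
#'
#' Mean temperature and prey concentrations of the night (surface,
#' 0 to `z_thermo` m) and day (sub-thermocline) layers, as experienced by
#' vertically migrating fish.
#'
#' @param state an `environment_state`.
#' @param cfg the [forcing_config()].
#' @return list with `T_surf`, `T_deep`, `micro_surf`, `meso_surf`
#'   (mgC m^-3 layer means) and `meso_night` (effective night-time
#'   mesozooplankton concentration in the surface layer, including the
#'   ascended share of the deep biomass).
#' @export
layer_stats <- function(state, cfg = forcing_config()) {
  surf <- state$depth <= cfg$z_thermo
  list(T_surf = mean(state$temperature[surf]),
       T_deep = mean(state$temperature[!surf]),
       micro_surf = mean(state$microzoo[surf]),
       meso_surf = mean(state$mesozoo[surf]),
       meso_night = (sum(state$mesozoo[surf]) +
                       cfg$night_ascent * sum(state$mesozoo[!surf])) /
         sum(surf))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
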