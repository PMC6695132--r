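# Configuration files, tabular writers and fixture generation.
# Configurations are YAML; tabular outputs are delimited text written at
# full double precision so that write/read round trips are exact.

# top-level and per-section keys accepted in a config file
#' @keywords internal
CONFIG_KEYS <- list(
  top = c("years", "spinup_years", "closure_month", "F_mult",
          "init_buffer_batches", "init_biomass", "species", "forcing"),
  species = c("n_adult_classes", "length_windows", "L_m", "lw", "T_opt",
              "Q_c", "T_max", "k_half", "DSF", "egg_energy", "E_egg",
              "sst_gate", "sst_threshold", "M", "F_adult", "ref_biomass",
              "init_lengths", "k_alloc", "atresia_days", "CAL_z", "CAL_f",
              "a_c", "b_c", "a_f", "a_e", "b_e", "a_sda", "resp"))

#' Load and validate a simulation configuration
#'
#' Reads a YAML configuration, overlays it on the package defaults
#' ([anchovy_params()], [sardine_params()], [forcing_config()]) and
#' validates every field through the type constructors.  Unknown keys
#' are rejected by name; out-of-range parameters raise the constructor's
#' validation error.
#'
#' @param path path to a YAML file.
#' @return a [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), CONFIG_KEYS$top)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  spp <- list(anchovy = anchovy_params(), sardine = sardine_params())
  for (sp in names(raw$species %||% list())) {
    if (!sp %in% names(spp)) stop("unknown species in config: ", sp)
    ov <- raw$species[[sp]]
    unknown <- setdiff(names(ov), CONFIG_KEYS$species)
    if (length(unknown))
      stop("unknown keys for species ", sp, ": ",
           paste(unknown, collapse = ", "))
    ctor <- if (sp == "anchovy") anchovy_params else sardine_params
    if (!is.null(ov$k_half)) ov$k_half <- lapply(ov$k_half, as.numeric)
    if (!is.null(ov$M)) ov$M <- unlist(ov$M)
    if (!is.null(ov$lw)) ov$lw <- unlist(ov$lw)
    spp[[sp]] <- do.call(ctor, ov)
  }
  fc <- do.call(forcing_config, raw$forcing %||% list())
  sim_config(species = spp, forcing = fc,
             years = raw$years %||% 30,
             spinup_years = raw$spinup_years %||% 10,
             closure_month = raw$closure_month,
             F_mult = if (!is.null(raw$F_mult)) unlist(raw$F_mult),
             init_biomass = raw$init_biomass,
             init_buffer_batches = raw$init_buffer_batches %||% 30)
}

#' Save a simulation configuration
#'
#' Writes the numeric/character fields of a [sim_config()] back to YAML
#' in the schema read by [load_config()], so that
#' `load_config(save_config(cfg, f))` reproduces `cfg`.
#'
#' @param config a [sim_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  sp_out <- lapply(config$species, function(p)
    list(n_adult_classes = p$n_adult_classes,
         length_windows = p$length_windows, L_m = p$L_m,
         lw = as.list(p$lw), T_opt = p$T_opt, Q_c = p$Q_c,
         T_max = p$T_max,
         k_half = lapply(p$k_half, as.numeric),
         DSF = p$DSF, egg_energy = p$egg_energy, E_egg = p$E_egg,
         sst_gate = p$sst_gate, sst_threshold = p$sst_threshold,
         M = as.numeric(p$M), F_adult = p$F_adult,
         ref_biomass = p$ref_biomass,
         init_lengths = p$init_lengths, k_alloc = p$k_alloc,
         atresia_days = p$atresia_days, CAL_z = p$CAL_z,
         CAL_f = p$CAL_f, a_c = p$a_c, b_c = p$b_c, a_f = p$a_f,
         a_e = p$a_e, b_e = p$b_e, a_sda = p$a_sda, resp = p$resp))
  fc <- config$forcing
  fc_out <- fc[c("sst_anchors", "T_deep", "z_thermo", "thermo_width",
                 "meso_low", "meso_peak", "meso_rise_start",
                 "meso_peak_day", "meso_crash_end", "micro_low",
                 "micro_peak", "micro_rise_start", "micro_peak_day",
                 "micro_crash_end", "deep_max_depth", "deep_max_width",
                 "surface_scale", "micro_surface_scale", "relax_rate",
                 "grazing_feedback", "habitat_area", "carbon_to_wet",
                 "n_bins", "max_depth", "day_fraction", "lowfeed_frac")]
  out <- list(years = config$years, spinup_years = config$spinup_years,
              closure_month = config$closure_month,
              F_mult = as.list(config$F_mult),
              init_buffer_batches = config$init_buffer_batches,
              species = sp_out, forcing = fc_out)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

# full-precision numeric formatting for exact round trips
#' @keywords internal
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write simulation output as a tidy time series
#'
#' One row per (day, species, metric): daily biomass (t), eggs released,
#' mean individual weight (g), per-stage abundance, plus day-level SST
#' and column-mean mesozooplankton (species = `"environment"`).  Numbers
#' are written at full double precision; [read_timeseries()] restores
#' them exactly.
#'
#' @param sim a `sim_result` from [run_simulation()].
#' @param path output path (tab-separated text).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(sim, path) {
  d <- sim$daily
  nd <- nrow(d$biomass)
  sp <- colnames(d$biomass)
  blocks <- list()
  for (s in sp) {
    for (m in c("biomass", "eggs", "eggs_recruit", "eggs_repeat",
                "mean_W"))
      blocks[[paste(s, m)]] <- data.frame(
        day = seq_len(nd), species = s, metric = m, value = d[[m]][, s],
        stringsAsFactors = FALSE)
  }
  blocks$sst <- data.frame(day = seq_len(nd), species = "environment",
                           metric = "sst", value = d$sst,
                           stringsAsFactors = FALSE)
  blocks$meso <- data.frame(day = seq_len(nd), species = "environment",
                            metric = "meso_colmean", value = d$meso_colmean,
                            stringsAsFactors = FALSE)
  tab <- do.call(rbind, blocks)
  tab$value <- fmt_num(tab$value)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param check.names passed through to [utils::read.delim()].
#' @export
read_timeseries <- function(path, check.names = TRUE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = check.names)
  tab$value <- as.numeric(tab$value)
  tab
}

#' Write a climatological forcing table
#'
#' Exports the synthetic climatology (or any environment history) as the
#' delimited forcing-table format accepted by [sim_config()] via
#' `forcing_table`: columns `day`, `depth`, `temperature`, `microzoo`,
#' `mesozoo`.
#'
#' @param cfg a [forcing_config()].
#' @param path output path.
#' @param days days of year to export (default every 5th day).
#' @return the exported data.frame, invisibly.
#' @export
write_forcing_table <- function(cfg, path, days = seq(1, 365, by = 5)) {
  rows <- lapply(days, function(d) {
    st <- seasonal_forcing(d, cfg)
    data.frame(day = d, depth = st$depth, temperature = st$temperature,
               microzoo = st$microzoo, mesozoo = st$mesozoo)
  })
  tab <- do.call(rbind, rows)
  out <- tab
  for (cc in c("temperature", "microzoo", "mesozoo"))
    out[[cc]] <- fmt_num(out[[cc]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

#' Read an external forcing table
#'
#' @param path delimited file with columns `day`, `depth`,
#'   `temperature`, `microzoo`, `mesozoo`.
#' @return validated data.frame.
#' @export
read_forcing_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("day", "depth", "temperature", "microzoo", "mesozoo")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("forcing table lacks columns: ", paste(miss, collapse = ", "))
  for (cc in need) tab[[cc]] <- as.numeric(tab[[cc]])
  if (any(tab$microzoo < 0) || any(tab$mesozoo < 0))
    stop("forcing table has negative concentrations")
  tab
}

#' Build daily climatology tables from a forcing table
#'
#' Interpolates an externally supplied forcing table onto the model's
#' depth bins and all 365 days (periodic linear interpolation in time,
#' nearest-bin matching in depth), returning the same structure as
#' [precompute_climate()] so user-supplied forcing can drive the
#' simulator.
#'
#' @param tab data.frame from [read_forcing_table()].
#' @param cfg a [forcing_config()] (grid and feedback settings still
#'   apply).
#' @return climatology tables (see [precompute_climate()]).
#' @export
climate_from_table <- function(tab, cfg = forcing_config()) {
  nb <- cfg$n_bins
  days <- sort(unique(tab$day))
  interp_day <- function(v, d) {
    xd <- c(days[length(days)] - 365, days, days[1] + 365)
    vv <- c(v[length(v)], v, v[1])
    stats::approx(xd, vv, xout = d)$y
  }
  fields <- c("temperature", "microzoo", "mesozoo")
  mats <- lapply(fields, function(f) matrix(0, nb, 365L))
  names(mats) <- fields
  # nearest source depth per model bin
  src_depths <- sort(unique(tab$depth))
  bin_src <- vapply(cfg$depth, function(z)
    src_depths[which.min(abs(src_depths - z))], 0)
  for (b in seq_len(nb)) {
    sub <- tab[tab$depth == bin_src[b], ]
    sub <- sub[order(sub$day), ]
    for (f in fields)
      mats[[f]][b, ] <- interp_day(sub[[f]], seq_len(365L))
  }
  surf <- cfg$depth <= cfg$z_thermo
  meso_cm <- colMeans(mats$mesozoo)
  list(K_micro = mats$microzoo, K_meso = mats$mesozoo,
       temp = mats$temperature, sst = mats$temperature[1, ],
       T_surf = colMeans(mats$temperature[surf, , drop = FALSE]),
       T_deep = colMeans(mats$temperature[!surf, , drop = FALSE]),
       surf = surf,
       micro_surf = colMeans(mats$microzoo[surf, , drop = FALSE]),
       meso_surf = colMeans(mats$mesozoo[surf, , drop = FALSE]),
       meso_night = (colSums(mats$mesozoo[surf, , drop = FALSE]) +
                       cfg$night_ascent *
                         colSums(mats$mesozoo[!surf, , drop = FALSE])) /
         sum(surf),
       lowfeed = meso_cm < cfg$lowfeed_frac * max(meso_cm))
}

#' Generate calibration and forcing fixtures
#'
#' Forward-simulates one super-individual per species with the shipped
#' (known) half-saturation coefficients and samples its weight at ages
#' spread through each stage's residency, producing the reference
#' size-at-age table consumed by [calibrate_full()]; also exports a
#' small forcing table exercising the file-input path.  With
#' `noise_sd > 0`, lognormal noise is added to the reference weights
#' using the seeded RNG; the default is noise-free so that parameter
#' recovery is exact up to GA convergence.
#'
#' @param seed RNG seed (used only for optional reference noise).
#' @param species named list of [species_params()] (defaults shipped).
#' @param forcing a [forcing_config()].
#' @param noise_sd lognormal sd of multiplicative reference noise.
#' @param points_per_stage reference points sampled per stage.
#' @return list with `size_at_age` (data.frame: species, stage,
#'   age_days, length_mm, weight_g) and `forcing` (data.frame as in
#'   [write_forcing_table()]).
#' @export
generate_fixtures <- function(seed = 1L,
                              species = list(anchovy = anchovy_params(),
                                             sardine = sardine_params()),
                              forcing = forcing_config(),
                              noise_sd = 0,
                              points_per_stage = 3L) {
  set.seed(seed)
  clim <- precompute_climate(forcing)
  rows <- list()
  for (sp in names(species)) {
    p <- species[[sp]]
    hatch <- if (p$sst_gate == "above") 152L else 335L
    # a second, late-season larval cohort samples a different seasonal
    # micro/mesozooplankton mix, which makes the two late-larva
    # half-saturation coefficients jointly identifiable
    cohorts <- list(main = hatch,
                    late_season = ((hatch + 59L) %% 365L) + 1L)
    for (cn in names(cohorts)) {
      hd <- cohorts[[cn]]
      larval_only <- cn != "main"
      n_days <- if (larval_only) 400L else (p$n_adult_classes + 1L) * 365L
      tr <- simulate_si(p, clim, hd, n_days, cfg = forcing)
      for (st in tuning_stages(p)) {
        lab <- st[1]
        if (larval_only && !lab %in% c("early", "late")) next
        code <- label_code(lab)
        days <- which(tr$stage == code)
        if (!length(days)) next
        qs <- unique(round(stats::quantile(days,
                                           probs = seq(0.3, 0.95,
                                                       length.out =
                                                         points_per_stage))))
        w <- tr$W[qs]
        if (noise_sd > 0)
          w <- w * exp(stats::rnorm(length(qs), 0, noise_sd))
        rows[[paste(sp, cn, lab)]] <- data.frame(
          species = sp, stage = lab, hatch_doy = hd, age_days = qs,
          length_mm = tr$L[qs], weight_g = w, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  fdays <- seq(1, 365, by = 10)
  frows <- lapply(fdays, function(d) {
    st <- seasonal_forcing(d, forcing)
    data.frame(day = d, depth = st$depth, temperature = st$temperature,
               microzoo = st$microzoo, mesozoo = st$mesozoo)
  })
  list(size_at_age = tab, forcing = do.call(rbind, frows))
}
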