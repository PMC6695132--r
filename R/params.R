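# Species parameter sets: stage structure, bioenergetics constants,
# reproduction and mortality parameters for anchovy and sardine.
#
# Stage indexing convention used throughout the package:
#   1 = embryo (egg + yolk-sac larva), 2 = early larva, 3 = late larva,
#   4 = juvenile, 5.. = adult age classes (5 = age-1, 6 = age-2, ...).

#' Stage code constants
#'
#' Integer stage codes used in super-individual state vectors.
#' @keywords internal
STAGE <- list(embryo = 1L, early = 2L, late = 3L, juvenile = 4L, adult1 = 5L)

#' Names of the feeding stages, in stage-code order starting at code 2
#' @keywords internal
FEEDING_STAGES <- c("early", "late", "juvenile", "adult")

#' Species parameter set
#'
#' Build the full parameter set for one species: stage length windows,
#' Wisconsin bioenergetics constants, length-weight relationship,
#' reproduction (fecundity, batch energy, SST spawning gate, energy
#' allocation split, atresia rule) and mortality rates.  Defaults are the
#' anchovy values; [anchovy_params()] and [sardine_params()] are the two
#' shipped parameterisations.
#'
#' Weight-specific rates use negative allometric exponents (`b_c`, `b_r`):
#' small larvae have much higher mass-specific maximum consumption and
#' respiration than adults, as in the Wisconsin model family.
#'
#' Half-saturation coefficients `k_half` (g prey m^-3, wet mass) are the
#' calibration targets of the genetic algorithm; the shipped defaults were
#' obtained by calibrating growth against the package's reference
#' size-at-age table under the default synthetic forcing.
#'
#' @param name species label.
#' @param n_adult_classes number of adult age classes (anchovy 3, sardine 4).
#' @param length_windows numeric vector `c(hatch, early_max, late_max, L_m)`
#'   in mm: stage boundaries for early larva, late larva, juvenile.
#' @param L_m length at maturity (mm).
#' @param lw length-weight coefficients `b0, b1, b2, d1, b3, d2` of the
#'   piecewise log10-log10 relation (length mm, weight g).
#' @param T_opt optimum temperature for consumption per feeding stage
#'   (early, late, juvenile, adult), degrees C.
#' @param Q_c consumption temperature-dependence slope per feeding stage.
#' @param T_max maximum temperature for consumption (C).
#' @param k_half list with elements `early` (microzoo), `late` (length 2:
#'   micro, meso), `juvenile` (meso), `adult` (meso, length
#'   `n_adult_classes`), all g prey m^-3.
#' @param DSF daily specific fecundity (eggs per g of spawner).
#' @param egg_energy egg energy content (carried as metadata; batch energy
#'   `E_egg` is supplied directly).
#' @param E_egg batch energy (g prey per g fish per day).
#' @param sst_gate `"above"` (spawn when SST > threshold) or `"below"`.
#' @param sst_threshold SST spawning threshold (C).
#' @param M natural mortality per stage (d^-1): embryo, early, late,
#'   juvenile, adult.
#' @param F_adult adult fishing mortality (d^-1).
#' @param ref_biomass reference population biomass (t) used to calibrate
#'   juvenile natural mortality.
#' @param init_lengths representative length (mm) of each adult age class
#'   used to seed the initial population.
#' @param k_alloc fraction of surplus energy routed to growth in mature
#'   fish (the remainder is stored in the reproductive buffer).
#' @param atresia_days consecutive deficit days that terminate the
#'   spawning season.
#' @param CAL_z,CAL_f caloric equivalents of zooplankton and fish
#'   (J g^-1 wet); only their ratio enters the growth equation.
#' @param resp list of respiration constants (see Details).
#' @param a_c,b_c intercept and exponent of maximum consumption.
#' @param a_f egestion fraction per feeding stage.
#' @param a_e,b_e excretion coefficients.
#' @param a_sda specific dynamic action coefficient.
#' @param embryo_dur function of temperature returning embryonic stage
#'   duration in days (default exponential decline; adopted functional
#'   form, configurable).
#'
#' @return an object of class `species_params`.
#' @export
species_params <- function(name,
                           n_adult_classes = 3L,
                           length_windows = c(4, 11, 42, 100),
                           L_m = 100,
                           lw = c(b0 = -6.1158, b1 = 3.5764, b2 = -0.616,
                                  d1 = 1.5798, b3 = 0.7137, d2 = 1.954),
                           T_opt = c(17.25, 16.25, 15.8, 15.8),
                           Q_c = c(2.22, 2.22, 2.4, 2.4),
                           T_max = 27,
                           k_half = list(early = 0.2, late = c(0.25, 0.25),
                                         juvenile = 0.6,
                                         adult = rep(0.6, n_adult_classes)),
                           DSF = 46,
                           egg_energy = 0.66,
                           E_egg = 0.012,
                           sst_gate = "above",
                           sst_threshold = 15,
                           M = c(embryo = 0.4, early = 0.2, late = 0.05,
                                 juvenile = 0.012, adult = 0.002),
                           F_adult = 0.00136,
                           ref_biomass = 40000,
                           init_lengths = c(120, 135, 145),
                           k_alloc = 0.5,
                           atresia_days = 9L,
                           CAL_z = 2580,
                           CAL_f = 5400,
                           a_c = 0.41, b_c = -0.31,
                           a_f = c(0.15, 0.15, 0.126, 0.126),
                           a_e = 0.41, b_e = 0.01, a_sda = 0.10,
                           resp = list(a_r = 0.003, b_r = -0.34, Q10 = 1.3,
                                       T_m = 16, d_r = 0.022,
                                       a_A_cold = 2.0, c_A_cold = 0.149,
                                       c_A_warm = 0.0,
                                       a_A_warm = c(12.25, 12.25, 11.98, 14.21),
                                       a_A_lowfeed = 9.97,
                                       b_A = c(0.27, 0.27, 0.33, 0.27)),
                           embryo_dur = NULL) {
  stopifnot(length(length_windows) == 4, all(diff(length_windows) > 0),
            length(T_opt) == 4, length(Q_c) == 4,
            all(T_opt < T_max),
            length(M) == 5, all(M >= 0), F_adult >= 0,
            k_alloc >= 0, k_alloc <= 1,
            DSF > 0, E_egg > 0, CAL_z > 0, CAL_f > 0,
            length(k_half$late) == 2,
            length(k_half$adult) == n_adult_classes,
            length(init_lengths) == n_adult_classes)
  if (any(unlist(k_half) <= 0))
    stop("all half-saturation coefficients must be positive")
  if (!sst_gate %in% c("above", "below"))
    stop("sst_gate must be 'above' or 'below'")
  if (is.null(embryo_dur))
    embryo_dur <- function(T) 22.3 * exp(-0.0875 * T)

  n_stages <- 4L + as.integer(n_adult_classes)
  p <- list(name = name,
            n_adult_classes = as.integer(n_adult_classes),
            n_stages = n_stages,
            length_windows = length_windows, L_m = L_m, lw = lw,
            T_opt = T_opt, Q_c = Q_c, T_max = T_max, k_half = k_half,
            DSF = DSF, egg_energy = egg_energy, E_egg = E_egg,
            sst_gate = sst_gate, sst_threshold = sst_threshold,
            M = unname(M), F_adult = F_adult, ref_biomass = ref_biomass,
            init_lengths = init_lengths,
            k_alloc = k_alloc, atresia_days = as.integer(atresia_days),
            CAL_z = CAL_z, CAL_f = CAL_f, cal_ratio = CAL_z / CAL_f,
            a_c = a_c, b_c = b_c, a_f = a_f, a_e = a_e, b_e = b_e,
            a_sda = a_sda, resp = resp, embryo_dur = embryo_dur)
  p <- c(p, stage_tables(p))
  structure(p, class = "species_params")
}

# Expand per-feeding-stage parameters into per-stage-code lookup vectors
# (index = stage code 1..n_stages); embryos get NA (they do not feed).
#' @keywords internal
stage_tables <- function(p) {
  nad <- p$n_adult_classes
  ns <- p$n_stages
  # feeding-stage index for codes 2,3,4 and all adult codes -> 1,2,3,4
  fidx <- c(NA, 1L, 2L, 3L, rep(4L, nad))
  pick <- function(x) c(NA, x[fidx[-1]])
  v_micro <- c(NA, 1, 0.5, 0, rep(0, nad))
  v_meso  <- c(NA, 0, 0.5, 1, rep(1, nad))
  k_micro <- c(NA, p$k_half$early, p$k_half$late[1], 1, rep(1, nad))
  k_meso  <- c(NA, 1, p$k_half$late[2], p$k_half$juvenile, p$k_half$adult)
  M_stage <- c(p$M[1:4], rep(p$M[5], nad))
  list(fidx = fidx,
       T_opt_stage = pick(p$T_opt), Q_c_stage = pick(p$Q_c),
       a_f_stage = pick(p$a_f),
       a_A_stage = pick(p$resp$a_A_warm), b_A_stage = pick(p$resp$b_A),
       v_micro = v_micro, v_meso = v_meso,
       k_micro = k_micro, k_meso = k_meso,
       M_stage = M_stage)
}

#' Rebuild stage lookup tables after changing a parameter
#'
#' Returns the parameter set with its derived per-stage lookup vectors
#' (vulnerabilities, half-saturations, mortalities) recomputed, e.g. after
#' assigning calibrated `k_half` values or a calibrated juvenile `M`.
#'
#' @param p a `species_params` object.
#' @return the updated `species_params` object.
#' @export
refresh_params <- function(p) {
  p[names(stage_tables(p))] <- stage_tables(p)
  p$cal_ratio <- p$CAL_z / p$CAL_f
  p
}

#' Anchovy parameter set
#'
#' European anchovy (*Engraulis encrasicolus*): summer spawner (SST > 15 C),
#' high daily specific fecundity (46 eggs g^-1), three adult age classes,
#' length at maturity 100 mm, stage windows 4-11-42-100 mm.
#'
#' @param ... overrides passed to [species_params()].
#' @return a `species_params` object.
#' @export
#' @examples
#' p <- anchovy_params()
#' p$DSF                       # 46 eggs per g
#' weight_from_length(120, p)  # ~12.6 g at 120 mm
anchovy_params <- function(...) {
  defaults <- list(
    name = "anchovy",
    n_adult_classes = 3L,
    length_windows = c(4, 11, 42, 100),
    L_m = 100,
    lw = c(b0 = -6.1158, b1 = 3.5764, b2 = -0.616,
           d1 = 1.5798, b3 = 0.7137, d2 = 1.954),
    T_opt = c(17.25, 16.25, 15.8, 15.8),
    k_half = list(early = 0.864, late = c(0.25, 0.20),
                  juvenile = 0.45, adult = c(1.2, 1.4, 1.3)),
    DSF = 46, egg_energy = 0.66, E_egg = 0.012,
    sst_gate = "above", sst_threshold = 15,
    M = c(embryo = 0.4, early = 0.2, late = 0.05,
          juvenile = 0.012, adult = 0.002),
    F_adult = 0.00136, ref_biomass = 40000,
    init_lengths = c(120, 135, 145))
  args <- utils::modifyList(defaults, list(...))
  do.call(species_params, args)
}

#' Sardine parameter set
#'
#' European sardine (*Sardina pilchardus*): winter spawner (SST < 16 C),
#' low daily specific fecundity (20.1 eggs g^-1), four adult age classes,
#' length at maturity 105 mm, stage windows 5-13-50-105 mm.  Shares all
#' bioenergetics constants with anchovy except the optimum temperatures
#' for larval consumption and the length-weight relationship.
#'
#' @param ... overrides passed to [species_params()].
#' @return a `species_params` object.
#' @export
sardine_params <- function(...) {
  defaults <- list(
    name = "sardine",
    n_adult_classes = 4L,
    length_windows = c(5, 13, 50, 105),
    L_m = 105,
    lw = c(b0 = -9.229, b1 = 5.391, b2 = -2.281,
           d1 = 1.699, b3 = 0.106, d2 = 2.02),
    T_opt = c(14.5, 14.75, 15.8, 15.8),
    k_half = list(early = 0.60, late = c(0.30, 0.15),
                  juvenile = 1.05, adult = c(1.6, 1.3, 1.3, 1.3)),
    DSF = 20.1, egg_energy = 1.11, E_egg = 0.0086,
    sst_gate = "below", sst_threshold = 16,
    M = c(embryo = 0.4, early = 0.2, late = 0.05,
          juvenile = 0.012, adult = 0.002),
    F_adult = 0.002, ref_biomass = 25000,
    init_lengths = c(130, 150, 165, 175))
  args <- utils::modifyList(defaults, list(...))
  do.call(species_params, args)
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("<species_params: %s>\n", x$name))
  cat(sprintf("  stages: embryo | %g-%g | %g-%g | %g-%g mm | %d adult classes\n",
              x$length_windows[1], x$length_windows[2],
              x$length_windows[2], x$length_windows[3],
              x$length_windows[3], x$length_windows[4],
              x$n_adult_classes))
  cat(sprintf("  L_m %g mm, DSF %g eggs/g, E_egg %g, SST gate %s %g C\n",
              x$L_m, x$DSF, x$E_egg, x$sst_gate, x$sst_threshold))
  cat(sprintf("  M: %s;  F_adult %g;  reference biomass %g t\n",
              paste(signif(x$M, 3), collapse = "/"), x$F_adult,
              x$ref_biomass))
  invisible(x)
}
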