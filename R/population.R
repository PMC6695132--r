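# Super-individual population bookkeeping.  Each species' population is a
# fixed pool of SI slots holding parallel state vectors; a stage code of 0
# marks an empty slot.  Stage caps (150 for embryo/early/late larvae, 10
# for juveniles and each adult age class) are enforced by merging the
# smallest-abundance SI into its nearest neighbour, which conserves
# abundance and biomass exactly.

#' Exponential survival under natural and fishing mortality
#'
#' Integrates `dN/dt = -(M + F) N` over `dt`: returns `N exp(-(M+F) dt)`.
#'
#' @param N abundance (>= 0; vectorised).
#' @param M natural mortality, d^-1.
#' @param F fishing mortality, d^-1 (adults only; pass 0 otherwise).
#' @param dt time step, days.
#' @return surviving abundance.
#' @export
#' @examples
#' apply_mortality(1000, 0.4, 0, 1)  # 1000 * exp(-0.4)
apply_mortality <- function(N, M, F = 0, dt = 1) {
  if (any(N < 0) || any(M < 0) || any(F < 0) || any(dt <= 0))
    stop("apply_mortality: N, M, F must be >= 0 and dt > 0")
  N * exp(-(M + F) * dt)
}

#' Starvation rule
#'
#' A super-individual dies (is removed) when cumulative weight loss from
#' its maximum attained weight exceeds the threshold (default 35%).
#'
#' @param W current weight, g.
#' @param W_max_seen maximum weight attained, g.
#' @param threshold fractional weight loss that kills (default 0.35).
#' @return logical vector: `TRUE` = alive.
#' @export
starvation_check <- function(W, W_max_seen, threshold = 0.35) {
  W >= (1 - threshold) * W_max_seen
}

#' Temperature-dependent embryonic duration
#'
#' Duration of the embryonic stage (egg plus yolk-sac larva) in days.
#' The functional form is configuration-supplied via
#' `params$embryo_dur` (default an exponential decline,
#' `22.3 exp(-0.0875 T)`, adopted from the model lineage rather than
#' fitted here); any positive, strictly decreasing function of
#' temperature can be substituted.
#'
#' @param T temperature, C, within 5-30.
#' @param params a [species_params()] object.
#' @return duration in days.
#' @export
embryonic_duration <- function(T, params) {
  if (any(T < 5 | T > 30)) stop("temperature outside plausible range 5-30 C")
  params$embryo_dur(T)
}

#' Diel vertical migration layer
#'
#' Eggs and early larvae stay in the surface layer (0-30 m) around the
#' clock; late larvae, juveniles and adults occupy the surface layer at
#' night and the sub-thermocline layer (>30 m) by day.
#'
#' @param stage stage code (1..n) or name.
#' @param hour hour of day, 0-23.
#' @param params a [species_params()] object (for stage-name resolution).
#' @return `"surface"` or `"deep"` (vectorised).
#' @export
dvm_layer <- function(stage, hour, params = anchovy_params()) {
  s <- if (is.character(stage)) {
    m <- c(embryo = 1L, early = 2L, late = 3L, juvenile = 4L, adult = 5L)
    unname(m[stage])
  } else as.integer(stage)
  daytime <- hour >= 6 & hour < 18
  ifelse(s <= 2L | !daytime, "surface", "deep")
}

#' Stage caps per stage code
#' @keywords internal
stage_caps <- function(params) {
  c(150L, 150L, 150L, 10L, rep(10L, params$n_adult_classes))
}

#' Create an empty super-individual population
#'
#' Allocates the fixed slot pool for one species (sum of the per-stage
#' caps) with parallel state vectors: `stage` (0 = empty), `N`, `W`, `L`,
#' `age` (days), `W_max_seen`, `dev` (embryonic development fraction) and
#' the reproductive state of [new_repro_state()].
#'
#' @param params a [species_params()] object.
#' @return an object of class `si_population`.
#' @export
new_population <- function(params) {
  n <- sum(stage_caps(params))
  pop <- c(list(stage = integer(n), N = numeric(n), W = numeric(n),
                L = numeric(n), age = numeric(n), W_max_seen = numeric(n),
                dev = numeric(n), veteran = logical(n),
                season_t0 = numeric(n),
                first_spawn = rep(NA_real_, n)),
           new_repro_state(n))
  structure(pop, class = "si_population", species = params$name)
}

#' @export
print.si_population <- function(x, ...) {
  alive <- x$stage > 0
  cat(sprintf("<si_population %s: %d live SIs, %.3g individuals, %.1f t>\n",
              attr(x, "species"), sum(alive), sum(x$N[alive]),
              sum(x$N[alive] * x$W[alive]) / 1e6))
  invisible(x)
}

# fields merged abundance-weighted; logical/integer fields inherited from
# the dominant (larger N) member
#' @keywords internal
MERGE_WEIGHTED <- c("W", "L", "age", "W_max_seen", "dev", "E_buffer",
                    "buf_start", "ar_cum", "egg_cum", "season_t0")
#' @keywords internal
MERGE_DOMINANT <- c("hunger_days", "season_open", "veteran")

# Merge SI j into SI i (same stage); slot j is freed.
#' @keywords internal
merge_si <- function(pop, i, j) {
  ni <- pop$N[i]; nj <- pop$N[j]; tot <- ni + nj
  if (tot > 0) {
    for (f in MERGE_WEIGHTED)
      pop[[f]][i] <- (pop[[f]][i] * ni + pop[[f]][j] * nj) / tot
    if (nj > ni)
      for (f in MERGE_DOMINANT) pop[[f]][i] <- pop[[f]][j]
    fs <- pop$first_spawn[c(i, j)]
    pop$first_spawn[i] <- if (all(is.na(fs))) NA_real_
      else if (anyNA(fs)) fs[!is.na(fs)]
      else (fs[1] * ni + fs[2] * nj) / tot
  }
  pop$N[i] <- tot
  pop$stage[j] <- 0L
  pop$N[j] <- 0
  pop
}

# Bring every stage back to its cap by merging the smallest-N SI into its
# nearest neighbour (by weight).
#' @keywords internal
enforce_caps <- function(pop, params) {
  caps <- stage_caps(params)
  counts <- tabulate(pop$stage, nbins = length(caps))
  for (s in which(counts > caps)) {
    while (counts[s] > caps[s]) {
      idx <- which(pop$stage == s)
      sm <- idx[which.min(pop$N[idx])]
      others <- setdiff(idx, sm)
      nb <- others[which.min(abs(pop$W[others] - pop$W[sm]))]
      pop <- merge_si(pop, nb, sm)
      counts[s] <- counts[s] - 1L
    }
  }
  pop
}

#' Admit a new super-individual, respecting stage caps
#'
#' Inserts the SI into a free slot; if the target stage is at its cap,
#' the incumbent with the smallest abundance is first merged into its
#' nearest neighbour (abundance-weighted means of weight, length, age and
#' reproductive stores), so total abundance and biomass are conserved.
#'
#' @param pop an `si_population`.
#' @param si named list with at least `stage`, `N`, `W`, `L`; optional
#'   `age`, `W_max_seen`, `dev`, `E_buffer` (default 0).
#' @param params a [species_params()] object.
#' @return the updated population.
#' @export
admit_si <- function(pop, si, params) {
  s <- as.integer(si$stage)
  stopifnot(s >= 1, s <= params$n_stages, si$N >= 0, si$W > 0)
  caps <- stage_caps(params)
  if (sum(pop$stage == s) >= caps[s]) {
    idx <- which(pop$stage == s)
    sm <- idx[which.min(pop$N[idx])]
    others <- setdiff(idx, sm)
    nb <- others[which.min(abs(pop$W[others] - pop$W[sm]))]
    pop <- merge_si(pop, nb, sm)
  }
  slot <- which(pop$stage == 0L)[1]
  if (is.na(slot)) stop("no free SI slot (total pool exhausted)")
  pop$stage[slot] <- s
  pop$N[slot] <- si$N
  pop$W[slot] <- si$W
  pop$L[slot] <- si$L
  pop$age[slot] <- si$age %||% 0
  pop$W_max_seen[slot] <- si$W_max_seen %||% si$W
  pop$dev[slot] <- si$dev %||% 0
  pop$veteran[slot] <- isTRUE(si$veteran)
  pop$E_buffer[slot] <- si$E_buffer %||% 0
  pop$hunger_days[slot] <- 0L
  pop$season_open[slot] <- FALSE
  pop$buf_start[slot] <- pop$ar_cum[slot] <- pop$egg_cum[slot] <- 0
  pop
}

#' Length- and age-based stage transitions
#'
#' Applies the one-way stage promotions: early larva to late larva and
#' late larva to juvenile at the species' stage length boundaries,
#' juvenile to adult age-1 at the length at maturity, and adult age-class
#' advancement on each 365-day age anniversary.  Super-individuals
#' leaving the terminal adult class are removed (senescence).  Embryo
#' hatching is driven by [embryonic_duration()] in the simulator, not
#' here.
#'
#' @param pop an `si_population`.
#' @param params a [species_params()] object.
#' @return list with `pop` (updated; caps re-enforced) and `newly_adult`
#'   (slot indices promoted to adulthood this call).
#' @export
stage_transition <- function(pop, params) {
  win <- params$length_windows
  nad <- params$n_adult_classes
  up <- pop$stage == 2L & pop$L >= win[2]
  pop$stage[up] <- 3L
  up <- pop$stage == 3L & pop$L >= win[3]
  pop$stage[up] <- 4L
  newly_adult <- which(pop$stage == 4L & pop$L >= params$L_m)
  if (length(newly_adult)) {
    cls <- pmin(pmax(floor(pop$age[newly_adult] / 365), 1), nad)
    pop$stage[newly_adult] <- 4L + as.integer(cls)
  }
  ad <- which(pop$stage >= 5L)
  if (length(ad)) {
    cls <- floor(pop$age[ad] / 365)
    dead <- cls > nad
    pop$stage[ad[dead]] <- 0L
    pop$N[ad[dead]] <- 0
    keep <- ad[!dead]
    pop$stage[keep] <- 4L + pmax(1L, as.integer(cls[!dead]))
  }
  pop <- enforce_caps(pop, params)
  list(pop = pop, newly_adult = newly_adult)
}

#' Population biomass in tonnes
#'
#' Biomass of the exploitable population (juveniles plus adults),
#' `sum(N W) / 1e6` tonnes.  Larval biomass is negligible and excluded,
#' matching acoustic-survey reference biomasses.
#'
#' @param pop an `si_population`.
#' @param stages stage codes to include (default juveniles and adults).
#' @return biomass in tonnes.
#' @export
biomass_t <- function(pop, stages = NULL) {
  if (is.null(stages)) sel <- pop$stage >= 4L
  else sel <- pop$stage %in% stages
  sum(pop$N[sel] * pop$W[sel]) / 1e6
}
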