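# Energy allocation / egg production algorithm.  Mature fish split any
# surplus after maintenance between somatic growth (fraction k) and a
# reproductive buffer (1 - k); immature fish put everything into growth.
# On deficit days the buffer is drained first (emergency maintenance),
# then soma.  Spawning requires the species SST gate, length above
# maturity, a buffer able to pay one egg batch, and an open season;
# nine consecutive deficit days close the season (atresia).
#
# Buffer units: absolute g prey per individual.  The specific allocation
# that appears in the growth equation is the absolute amount divided by
# the individual weight.

#' Create reproductive state vectors
#'
#' @param n number of super-individuals.
#' @return list of parallel vectors: `E_buffer` (g prey per individual),
#'   `hunger_days`, `season_open`, `buf_start`, `ar_cum` (cumulative
#'   emergency maintenance paid from the buffer this season), `egg_cum`
#'   (cumulative egg energy spent this season).
#' @export
new_repro_state <- function(n) {
  list(E_buffer = numeric(n), hunger_days = integer(n),
       season_open = logical(n), buf_start = numeric(n),
       ar_cum = numeric(n), egg_cum = numeric(n))
}

#' Allocate surplus energy between growth and the reproductive buffer
#'
#' For surplus `A >= 0`: immature fish (`L < L_m`) grow with all of it;
#' mature fish grow with `k A` and deposit `(1 - k) A W` into the buffer.
#' For `A < 0` the deficit is paid from the buffer first (logged into the
#' season's emergency-maintenance accumulator `ar_cum`), the remainder
#' from soma as negative growth.  The buffer never goes negative.
#'
#' All arguments are vectorised over super-individuals.
#'
#' @param A surplus after maintenance, g prey g^-1 d^-1.
#' @param W individual weight, g.
#' @param L individual length, mm.
#' @param state reproductive state from [new_repro_state()].
#' @param params a [species_params()] object.
#' @return list with `growth` (specific growth allocation, may be
#'   negative), `E_buffer_alloc` (specific buffer flux for the budget
#'   identity: positive deposit, negative draw) and `state` (updated).
#' @export
allocate_energy <- function(A, W, L, state, params) {
  k <- params$k_alloc
  mature <- L >= params$L_m
  pos <- A >= 0
  growth <- ifelse(pos, ifelse(mature, k * A, A), 0)
  deposit <- ifelse(pos & mature, (1 - k) * A * W, 0)
  need <- ifelse(pos, 0, -A * W)
  draw <- pmin(state$E_buffer, need)
  growth <- growth - (need - draw) / W
  state$E_buffer <- state$E_buffer + deposit - draw
  state$ar_cum <- state$ar_cum + draw
  list(growth = growth,
       E_buffer_alloc = deposit / W - draw / W,
       state = state)
}

#' Species SST spawning gate
#'
#' @param sst sea-surface temperature, C.
#' @param params a [species_params()] object (`sst_gate`, `sst_threshold`).
#' @return logical: is the SST criterion satisfied?
#' @export
sst_gate_open <- function(sst, params) {
  if (params$sst_gate == "above") sst > params$sst_threshold
  else sst < params$sst_threshold
}

#' Daily spawning decision
#'
#' A super-individual spawns today iff the species SST rule holds, its
#' length exceeds the length at maturity, its buffer can pay one egg
#' batch (`E_buffer >= E_egg W`) and its spawning season has not been
#' closed by atresia.
#'
#' @param sst sea-surface temperature, C (scalar).
#' @param L,W length (mm) and weight (g) vectors.
#' @param state reproductive state.
#' @param params a [species_params()] object.
#' @return logical vector.
#' @export
spawn_decision <- function(sst, L, W, state, params) {
  sst_gate_open(sst, params) &
    L > params$L_m &
    state$E_buffer >= params$E_egg * W &
    state$season_open
}

#' Update the hunger counter and apply the atresia rule
#'
#' A day on which intake plus the reproductive buffer fail to cover
#' maintenance (the soma shrinks) counts as a deficit day;
#' `atresia_days` consecutive deficit days terminate the spawning season
#' of an individual that has begun spawning (atresia is the resorption
#' of developing eggs, so it can only end a season with egg production
#' under way).  Sufficient days reset the counter.
#'
#' @param state reproductive state (uses `egg_cum` to tell whether the
#'   season has begun).
#' @param deficit logical vector: was today a deficit day?
#' @param params a [species_params()] object.
#' @return updated state (with `season_open` possibly cleared).
#' @export
update_hunger <- function(state, deficit, params) {
  state$hunger_days <- ifelse(deficit, state$hunger_days + 1L, 0L)
  state$season_open <- state$season_open &
    (state$hunger_days < params$atresia_days | state$egg_cum <= 0)
  state
}

#' Release an egg batch
#'
#' Eggs per individual equal `DSF * W`; the egg super-individual's
#' population is `DSF * W * N`.  The buffer is debited by the batch
#' energy `E_egg * W`, which is added to the season's egg-energy
#' accumulator.
#'
#' @param W,N weight (g) and abundance of the spawning super-individuals
#'   (vectorised).
#' @param state reproductive state.
#' @param params a [species_params()] object.
#' @return list with `eggs_per_ind`, `egg_pop` (eggs released per SI,
#'   i.e. `DSF * W * N`) and `state` (buffer debited).
#' @export
release_batch <- function(W, N, state, params) {
  debit <- params$E_egg * W
  if (any(state$E_buffer < debit - 1e-9 * pmax(debit, 1)))
    stop("release_batch called with insufficient buffer: ",
         "spawn_decision/bookkeeping inconsistency")
  state$E_buffer <- pmax(state$E_buffer - debit, 0)
  state$egg_cum <- state$egg_cum + debit
  list(eggs_per_ind = params$DSF * W,
       egg_pop = params$DSF * W * N,
       state = state)
}

#' Open a new spawning season
#'
#' Resets the season accumulators: records the buffer at season start,
#' zeroes the emergency-maintenance and egg-energy accumulators and the
#' hunger counter, and reopens the season.
#'
#' @param state reproductive state.
#' @param idx indices of super-individuals entering the season (default
#'   all).
#' @return updated state.
#' @export
season_start <- function(state, idx = seq_along(state$E_buffer)) {
  state$buf_start[idx] <- state$E_buffer[idx]
  state$ar_cum[idx] <- 0
  state$egg_cum[idx] <- 0
  state$hunger_days[idx] <- 0L
  state$season_open[idx] <- TRUE
  state
}

#' Capital index
#'
#' Locates a spawner on the capital-income breeding continuum:
#' `(buffer at season start - buffer at season end - sum of emergency
#' maintenance paid from the buffer) / (cumulative egg energy spent)`.
#' 1 means all egg energy came from the pre-season store (pure capital
#' breeding); 0 means it was all covered by concurrent intake (income
#' breeding).  Undefined (NA) when no egg energy was spent.
#'
#' @param buf_start,buf_end buffer at season start and end (g prey).
#' @param ar_cum cumulative emergency maintenance paid from the buffer.
#' @param egg_cum cumulative egg energy spent.
#' @return dimensionless index (NA where `egg_cum <= 0`).
#' @export
#' @examples
#' capital_index(10, 0, 2, 16)  # 0.5
capital_index <- function(buf_start, buf_end, ar_cum, egg_cum) {
  ifelse(egg_cum > 0, (buf_start - buf_end - ar_cum) / egg_cum, NA_real_)
}
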