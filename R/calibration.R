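# Calibration: a real-coded genetic algorithm tunes the stage-/age-
# specific half-saturation coefficients against reference weights-at-age
# (sequentially, youngest stage first, with earlier stages frozen), and a
# bracketing bisection calibrates juvenile natural mortality so that the
# simulated population fluctuates around its reference biomass.

#' Genetic-algorithm configuration
#'
#' @param pop_size chromosomes per generation.
#' @param crossover_rate probability that a selected pair undergoes
#'   uniform crossover.
#' @param mutation_rate per-gene probability of Gaussian mutation.
#' @param mutation_sd initial mutation standard deviation, as a fraction
#'   of the gene's bound range.
#' @param mutation_decay multiplicative decay of the mutation scale per
#'   generation (annealing; lets the population converge so that the
#'   mean-fitness stagnation rule can fire).
#' @param max_generations hard generation cap (default 1000).
#' @param stagnation_window generations of unchanged mean fitness that
#'   stop the run early (default 150).
#' @param stagnation_tol relative tolerance for "unchanged" mean fitness.
#' @param elitism number of best chromosomes copied unchanged.
#' @param tournament tournament size for selection.
#' @param lower,upper default gene bounds (g prey m^-3).
#' @param seed RNG seed used for the whole GA run.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 50, crossover_rate = 0.9,
                      mutation_rate = 0.25, mutation_sd = 0.15,
                      mutation_decay = 0.98,
                      max_generations = 1000L, stagnation_window = 150L,
                      stagnation_tol = 1e-9,
                      elitism = 1L, tournament = 2L,
                      lower = 0.02, upper = 6, seed = 1L) {
  stopifnot(pop_size >= 4, max_generations >= 1,
            stagnation_window < max_generations,
            lower > 0, upper > lower)
  structure(as.list(environment()), class = "ga_config")
}

#' Calibration fitness
#'
#' `1 / (sum((prediction - reference)^2) + eps)`: the reciprocal squared
#' Euclidean distance between predicted and reference weights-at-age,
#' with a small floor `eps` so that an exact fit yields a finite maximal
#' score.  Larger is better.
#'
#' @param predicted,reference aligned numeric vectors (non-empty).
#' @param eps floor added to the squared distance (default 1e-12).
#' @return the fitness score.
#' @export
#' @examples
#' fitness(c(1, 2), c(2, 3))  # 1 / (1 + 1) = 0.5
fitness <- function(predicted, reference, eps = 1e-12) {
  if (!length(predicted) || length(predicted) != length(reference))
    stop("predicted and reference must be non-empty and aligned")
  1 / (sum((predicted - reference)^2) + eps)
}

#' Real-coded genetic algorithm (maximiser)
#'
#' Tournament selection, uniform crossover, annealed Gaussian mutation,
#' elitism.  Terminates at `max_generations` or when the population mean
#' fitness is unchanged (to `stagnation_tol`, relative) for
#' `stagnation_window` consecutive generations.
#'
#' @param fn objective: function of a parameter vector, to maximise.
#' @param lower,upper gene bounds (recycled to the gene count).
#' @param n_genes number of genes.
#' @param cfg a [ga_config()].
#' @return list with `par` (best chromosome), `value`, `generations`,
#'   `terminated` (`"max_generations"` or `"stagnation"`), `trace_best`
#'   and `trace_mean` (per-generation fitness traces).
#' @export
ga_optimize <- function(fn, lower, upper, n_genes = length(lower),
                        cfg = ga_config()) {
  lower <- rep_len(lower, n_genes); upper <- rep_len(upper, n_genes)
  set.seed(cfg$seed)
  np <- cfg$pop_size
  pop <- matrix(stats::runif(np * n_genes, lower, upper), np, n_genes,
                byrow = TRUE)
  fit <- apply(pop, 1, fn)
  trace_best <- trace_mean <- numeric(0)
  stag <- 0L
  terminated <- "max_generations"
  gen <- 0L
  range_ <- upper - lower
  for (gen in seq_len(cfg$max_generations)) {
    trace_best <- c(trace_best, max(fit))
    m <- mean(fit)
    if (length(trace_mean) &&
        abs(m - trace_mean[length(trace_mean)]) <=
          cfg$stagnation_tol * max(abs(m), 1e-300)) {
      stag <- stag + 1L
    } else stag <- 0L
    trace_mean <- c(trace_mean, m)
    if (stag >= cfg$stagnation_window) {
      terminated <- "stagnation"
      break
    }
    if (gen == cfg$max_generations) break
    # selection (tournament)
    pick <- function() {
      cand <- sample.int(np, cfg$tournament, replace = TRUE)
      cand[which.max(fit[cand])]
    }
    elite_idx <- order(fit, decreasing = TRUE)[seq_len(cfg$elitism)]
    newpop <- matrix(0, np, n_genes)
    newpop[seq_len(cfg$elitism), ] <- pop[elite_idx, , drop = FALSE]
    i <- cfg$elitism + 1L
    while (i <= np) {
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      if (stats::runif(1) < cfg$crossover_rate) {
        swap <- stats::runif(n_genes) < 0.5
        tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
      }
      newpop[i, ] <- p1
      if (i + 1L <= np) newpop[i + 1L, ] <- p2
      i <- i + 2L
    }
    # annealed Gaussian mutation (elites exempt)
    sd_now <- cfg$mutation_sd * cfg$mutation_decay^gen
    for (r in (cfg$elitism + 1L):np) {
      mut <- stats::runif(n_genes) < cfg$mutation_rate
      if (any(mut))
        newpop[r, mut] <- newpop[r, mut] +
          stats::rnorm(sum(mut), 0, sd_now * range_[mut])
    }
    newpop <- pmin(pmax(newpop, matrix(lower, np, n_genes, byrow = TRUE)),
                   matrix(upper, np, n_genes, byrow = TRUE))
    pop <- newpop
    fit <- apply(pop, 1, fn)
  }
  best <- which.max(fit)
  list(par = pop[best, ], value = fit[best], generations = gen,
       terminated = terminated, trace_best = trace_best,
       trace_mean = trace_mean)
}

# Stage labels in tuning order and their gene counts
#' @keywords internal
tuning_stages <- function(params) {
  c(list(c("early", 1L), c("late", 2L), c("juvenile", 1L)),
    lapply(seq_len(params$n_adult_classes),
           function(a) c(paste0("adult", a), 1L)))
}

# Assign a chromosome's genes to params$k_half for one stage label.
#' @keywords internal
set_stage_k <- function(params, label, k) {
  if (label == "early") params$k_half$early <- k
  else if (label == "late") params$k_half$late <- k
  else if (label == "juvenile") params$k_half$juvenile <- k
  else {
    a <- as.integer(sub("adult", "", label))
    params$k_half$adult[a] <- k
  }
  refresh_params(params)
}

#' @keywords internal
get_stage_k <- function(params, label) {
  if (label == "early") params$k_half$early
  else if (label == "late") params$k_half$late
  else if (label == "juvenile") params$k_half$juvenile
  else params$k_half$adult[as.integer(sub("adult", "", label))]
}

# Stage code occupied while the focal label's k applies.
#' @keywords internal
label_code <- function(label) {
  switch(label, early = 2L, late = 3L, juvenile = 4L,
         4L + as.integer(sub("adult", "", label)))
}

#' Tune the half-saturation coefficient(s) of one stage
#'
#' Runs the genetic algorithm for the focal stage with all earlier
#' stages' coefficients frozen, using the single-super-individual forward
#' harness: each chromosome is evaluated by simulating one individual
#' from the (frozen) focal-stage entry state and scoring predicted
#' weights at the reference ages with [fitness()].
#'
#' @param params a [species_params()] with earlier stages already tuned.
#' @param label focal stage: `"early"`, `"late"`, `"juvenile"`,
#'   `"adult1"`, `"adult2"`, ...
#' @param reference data.frame with columns `stage` (label), `age_days`,
#'   `weight_g`; rows for the focal label are the fitting targets.
#' @param ga_cfg a [ga_config()].
#' @param forcing a [forcing_config()].
#' @param hatch_doy hatch day of year of the reference individual.
#' @return list with `k` (tuned value(s)), `ga` (the [ga_optimize()]
#'   result) and `params` (updated).
#' @export
tune_stage <- function(params, label, reference, ga_cfg = ga_config(),
                       forcing = forcing_config(), hatch_doy = NULL) {
  ref <- reference[reference$stage == label, ]
  if (!nrow(ref)) stop("no reference data for stage ", label)
  if (is.null(hatch_doy))
    hatch_doy <- if (params$sst_gate == "above") 152L else 335L
  if (is.null(ref$hatch_doy)) ref$hatch_doy <- hatch_doy
  clim <- precompute_climate(forcing)
  code <- label_code(label)
  # one frozen upstream trajectory per reference cohort (hatch date)
  cohorts <- lapply(split(ref, ref$hatch_doy), function(rr) {
    hd <- rr$hatch_doy[1]
    if (code == 2L) {
      entry <- list(state = NULL, age = 0)
    } else {
      probe <- simulate_si(params, clim, hd,
                           n_days = max(rr$age_days) + 30L, cfg = forcing)
      t_entry <- match(TRUE, probe$stage >= code)
      if (is.na(t_entry))
        stop("trajectory never reaches stage ", label,
             " within the reference horizon")
      up <- simulate_si(params, clim, hd, n_days = t_entry, cfg = forcing)
      entry <- list(state = up$state, age = t_entry)
    }
    horizon <- max(rr$age_days) - entry$age
    if (horizon < 1)
      stop("reference ages precede entry into stage ", label)
    list(hd = hd, entry = entry, horizon = horizon, ref = rr)
  })
  n_genes <- if (label == "late") 2L else 1L
  objective <- function(k) {
    p2 <- set_stage_k(params, label, k)
    sse <- 0
    for (co in cohorts) {
      tr <- simulate_si(p2, clim, co$hd, n_days = co$horizon,
                        cfg = forcing, state = co$entry$state)
      pred <- tr$W[co$ref$age_days - co$entry$age]
      sse <- sse + sum((pred - co$ref$weight_g)^2)
    }
    1 / (sse + 1e-12)
  }
  ga <- ga_optimize(objective, lower = ga_cfg$lower, upper = ga_cfg$upper,
                    n_genes = n_genes, cfg = ga_cfg)
  list(k = ga$par, ga = ga, params = set_stage_k(params, label, ga$par))
}

#' Sequential (or simultaneous) calibration of all stages
#'
#' Applies [tune_stage()] from the youngest stage to the terminal adult
#' age class, freezing each tuned coefficient before moving on
#' (`mode = "sequential"`, the default), or tunes all coefficients in a
#' single GA run (`mode = "simultaneous"`, for comparison).
#'
#' @param params a [species_params()].
#' @param reference data.frame (`stage`, `age_days`, `weight_g`) covering
#'   every stage.
#' @param ga_cfg a [ga_config()]; in sequential mode stage `i` uses seed
#'   `seed + i - 1`.
#' @param ga_cfg_late GA configuration for the two-gene late-larva
#'   stage; its two half-saturation coefficients lie on a shallow,
#'   curved fitness valley (many micro/meso combinations yield similar
#'   total intake), so this stage defaults to a larger population with
#'   slower mutation annealing than the one-dimensional stages.
#' @param forcing a [forcing_config()].
#' @param hatch_doy hatch day of year (default: species spawning season).
#' @param mode `"sequential"` or `"simultaneous"`.
#' @return an object of class `calibration_result`: list with `params`
#'   (tuned), `k` (named list per stage), `ga` (per-stage GA results or
#'   the single simultaneous run), `sse` (final sum of squared
#'   deviations over all reference points) and `predicted`
#'   (reference table with a `predicted_g` column).
#' @export
calibrate_full <- function(params, reference, ga_cfg = ga_config(),
                           ga_cfg_late = NULL,
                           forcing = forcing_config(), hatch_doy = NULL,
                           mode = c("sequential", "simultaneous")) {
  mode <- match.arg(mode)
  if (is.null(ga_cfg_late)) {
    ga_cfg_late <- ga_cfg
    ga_cfg_late$pop_size <- max(ga_cfg$pop_size, 30)
    ga_cfg_late$mutation_decay <- max(ga_cfg$mutation_decay, 0.94)
    ga_cfg_late$elitism <- max(ga_cfg$elitism, 2L)
  }
  if (is.null(hatch_doy))
    hatch_doy <- if (params$sst_gate == "above") 152L else 335L
  if (is.null(reference$hatch_doy)) reference$hatch_doy <- hatch_doy
  stages <- tuning_stages(params)
  labels <- vapply(stages, `[[`, "", 1)
  missing <- setdiff(unique(reference$stage), labels)
  if (length(missing))
    stop("reference rows with unknown stage label: ",
         paste(missing, collapse = ", "))
  clim <- precompute_climate(forcing)
  predict_ref <- function(p2) {
    pred <- numeric(nrow(reference))
    for (hd in unique(reference$hatch_doy)) {
      sel <- reference$hatch_doy == hd
      tr <- simulate_si(p2, clim, hd,
                        n_days = max(reference$age_days[sel]),
                        cfg = forcing)
      pred[sel] <- tr$W[reference$age_days[sel]]
    }
    pred
  }
  gas <- list()
  if (mode == "sequential") {
    for (i in seq_along(stages)) {
      lab <- labels[i]
      if (!any(reference$stage == lab))
        stop("missing reference data for stage ", lab)
      cfg_i <- if (lab == "late") ga_cfg_late else ga_cfg
      cfg_i$seed <- ga_cfg$seed + i - 1L
      tuned <- tune_stage(params, lab, reference, cfg_i, forcing,
                          hatch_doy)
      params <- tuned$params
      gas[[lab]] <- tuned$ga
    }
  } else {
    n_per <- vapply(stages, function(s) as.integer(s[2]), 1L)
    offsets <- cumsum(c(0L, n_per[-length(n_per)]))
    objective <- function(kk) {
      p2 <- params
      for (i in seq_along(stages))
        p2 <- set_stage_k(p2, labels[i],
                          kk[offsets[i] + seq_len(n_per[i])])
      fitness(predict_ref(p2), reference$weight_g)
    }
    ga <- ga_optimize(objective, lower = ga_cfg$lower,
                      upper = ga_cfg$upper, n_genes = sum(n_per),
                      cfg = ga_cfg)
    for (i in seq_along(stages))
      params <- set_stage_k(params, labels[i],
                            ga$par[offsets[i] + seq_len(n_per[i])])
    gas <- list(simultaneous = ga)
  }
  pred <- predict_ref(params)
  out <- reference
  out$predicted_g <- pred
  structure(list(params = params,
                 k = params$k_half,
                 ga = gas,
                 sse = sum((pred - reference$weight_g)^2),
                 predicted = out),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n  tuned k_half:\n")
  cat(sprintf("    early %.3f | late %.3f/%.3f | juvenile %.3f | adult %s\n",
              x$k$early, x$k$late[1], x$k$late[2], x$k$juvenile,
              paste(sprintf("%.3f", x$k$adult), collapse = "/")))
  cat(sprintf("  final SSE: %.4g over %d reference points\n", x$sse,
              nrow(x$predicted)))
  invisible(x)
}

#' Calibrate juvenile natural mortality against a reference biomass
#'
#' Bracketing bisection on the focal species' juvenile `M` such that the
#' mean post-spin-up biomass of a coupled run matches the target within
#' `tol` (relative).  Mean biomass must be monotone decreasing in `M`
#' over the bracket; the endpoints are checked to straddle the target
#' and the bisection trace is checked for monotonicity.
#'
#' @param config a [sim_config()]; the run length and spin-up of the
#'   bisection evaluations are taken from it.
#' @param species name of the species whose juvenile `M` is calibrated.
#' @param target target mean biomass, t (default the species' reference
#'   biomass).
#' @param bracket initial `c(low, high)` for `M` (d^-1).
#' @param tol relative tolerance on the mean biomass (default 0.05).
#' @param max_iter maximum bisection iterations.
#' @return list with `M` (calibrated), `biomass` (achieved mean),
#'   `trace` (data.frame `M`, `biomass` of all evaluations),
#'   `converged`.
#' @export
calibrate_juvenile_M <- function(config, species,
                                 target = NULL,
                                 bracket = c(5e-4, 0.1),
                                 tol = 0.05, max_iter = 12L) {
  p <- config$species[[species]]
  if (is.null(p)) stop("unknown species ", species)
  target <- target %||% p$ref_biomass
  stopifnot(target > 0, bracket[1] > 0, bracket[2] > bracket[1])
  eval_M <- function(M) {
    cf <- config
    cf$record_abundance <- FALSE  # evaluations only need biomass
    cf$species[[species]]$M[4] <- M
    cf$species[[species]] <- refresh_params(cf$species[[species]])
    mean_biomass(run_simulation(cf), species)
  }
  lo <- bracket[1]; hi <- bracket[2]
  b_lo <- eval_M(lo); b_hi <- eval_M(hi)
  trace <- data.frame(M = c(lo, hi), biomass = c(b_lo, b_hi))
  if (!(b_lo > target && target > b_hi)) {
    stop("target biomass ", target, " t not bracketed: biomass at M=",
         lo, " is ", round(b_lo), " t, at M=", hi, " is ",
         round(b_hi), " t")
  }
  for (it in seq_len(max_iter)) {
    M_mid <- sqrt(lo * hi)  # geometric midpoint: M spans orders of magnitude
    b_mid <- eval_M(M_mid)
    trace <- rbind(trace, data.frame(M = M_mid, biomass = b_mid))
    if (abs(b_mid - target) / target <= tol) break
    if (b_mid > target) lo <- M_mid else hi <- M_mid
  }
  ord <- order(trace$M)
  if (any(diff(trace$biomass[ord]) > 0.02 * target))
    warning("mean biomass is not monotone decreasing in M over the ",
            "bisection trace")
  # population dynamics are deterministic but sensitively dependent on M,
  # so the best point visited, not the last midpoint, is returned
  best <- which.min(abs(trace$biomass - target))
  list(M = trace$M[best], biomass = trace$biomass[best],
       trace = trace[ord, ],
       converged = abs(trace$biomass[best] - target) / target <= tol)
}

#' Calibrate the reference baseline state
#'
#' The package's standard baseline-calibration driver: alternating
#' juvenile-M bisections over the full simulation protocol
#' ([calibrate_baseline()]), followed, when a species' mean biomass is
#' still outside the tolerance, by one narrow-bracket polish per such
#' species; the polished parameter set is kept only if it reduces the
#' worst relative biomass error of the confirming run.
#'
#' @param config a [sim_config()] (defines the protocol: years, spin-up,
#'   forcing).
#' @param passes,tol,... see [calibrate_baseline()] /
#'   [calibrate_juvenile_M()].
#' @param polish_factor bracket half-width factor of the polish stage.
#' @return list with `config`, `sim` (the confirming run of the chosen
#'   configuration) and `details`.
#' @export
calibrate_reference_state <- function(config, passes = 2, tol = 0.05,
                                      polish_factor = 1.15, ...) {
  cal <- calibrate_baseline(config, passes = passes, tol = tol, ...)
  cfg <- cal$config
  sim <- run_simulation(cfg)
  err <- function(s) {
    vapply(names(s$config$species), function(sp)
      abs(mean_biomass(s, sp) - s$config$species[[sp]]$ref_biomass) /
        s$config$species[[sp]]$ref_biomass, 0)
  }
  e0 <- err(sim)
  off <- names(which(e0 > tol))
  if (length(off)) {
    cfg2 <- cfg
    for (sp in off) {
      res <- tryCatch(
        calibrate_juvenile_M(cfg2, sp,
                             bracket = cfg2$species[[sp]]$M[4] *
                               c(1 / polish_factor, polish_factor),
                             tol = tol, ...),
        error = function(e) NULL)
      if (!is.null(res)) {
        cfg2$species[[sp]]$M[4] <- res$M
        cfg2$species[[sp]] <- refresh_params(cfg2$species[[sp]])
        cal$details[[sp]] <- res
      }
    }
    sim2 <- run_simulation(cfg2)
    if (max(err(sim2)) < max(e0)) {
      cfg <- cfg2
      sim <- sim2
    }
  }
  list(config = cfg, sim = sim, details = cal$details)
}

#' Calibrate juvenile M for every species in a configuration
#'
#' Applies [calibrate_juvenile_M()] species by species over `passes`
#' alternating rounds (each calibration sees the others' current
#' values; later rounds refine within a narrow bracket around the
#' incumbent), returning the updated configuration.
#'
#' @param config a [sim_config()].
#' @param passes alternating calibration rounds over the species.
#' @param bracket initial wide bracket for the first round.
#' @param refine_factor later rounds bracket the incumbent by
#'   `M * refine_factor^c(-1, 1)`.
#' @param ... passed to [calibrate_juvenile_M()].
#' @return list with `config` (calibrated) and `details` (per-species
#'   calibration results of the final round).
#' @export
calibrate_baseline <- function(config, passes = 2, bracket = c(5e-4, 0.03),
                               refine_factor = 1.4, ...) {
  details <- list()
  for (pass in seq_len(passes)) {
    for (sp in names(config$species)) {
      br <- if (pass == 1) bracket
        else config$species[[sp]]$M[4] * c(1 / refine_factor, refine_factor)
      res <- tryCatch(calibrate_juvenile_M(config, sp, bracket = br, ...),
                      error = function(e) e)
      if (inherits(res, "error")) {
        if (pass == 1) stop(res)
        res <- calibrate_juvenile_M(config, sp, bracket = bracket, ...)
      }
      config$species[[sp]]$M[4] <- res$M
      config$species[[sp]] <- refresh_params(config$species[[sp]])
      details[[sp]] <- res
    }
  }
  list(config = config, details = details)
}
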