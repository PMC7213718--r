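#' Genome layout for a given forward model and PCL set
#'
#' The search point of the optimizer. For the ionic model it holds the 13
#' multiplicative scaling factors plus, for every pacing cycle length, the
#' initial values of the slow state variables `[Na+]i` (mM) and `[Ca2+]NSR`
#' (mM), which are co-optimized so that the fitted model is at pacing steady
#' state. For the toy model it holds its 4 shape multipliers.
#'
#' @param mode `"cell"`, `"cable"` or `"toy"`.
#' @param pcls pacing cycle lengths of the baseline set (ms).
#' @return list: `names`, `lower`, `upper` (per-gene bounds), `base`
#'   (normalization constants used by the mutation operator; multipliers are
#'   already baseline-normalized, slow genes are divided by the published
#'   resting values).
#' @export
genome_spec <- function(mode = c("cell", "cable", "toy"), pcls = numeric()) {
  mode <- match.arg(mode)
  if (mode == "toy") {
    nm <- names(toy_reference())
    return(list(names = nm,
                lower = stats::setNames(rep(0.01, 4), nm),
                upper = stats::setNames(rep(4, 4), nm),
                base = stats::setNames(rep(1, 4), nm),
                n_scaling = 4L, mode = mode, pcls = pcls))
  }
  init <- ord_initial_state()
  nm <- c(scaling_names(),
          paste0("nai_", pcls), paste0("cansr_", pcls))
  k <- length(pcls)
  lower <- c(rep(0.01, 13), rep(1, k), rep(0.3, k))
  upper <- c(rep(4, 13), rep(20, k), rep(6, k))
  base <- c(rep(1, 13), rep(init[["nai"]], k), rep(init[["cansr"]], k))
  list(names = nm, lower = stats::setNames(lower, nm),
       upper = stats::setNames(upper, nm),
       base = stats::setNames(base, nm),
       n_scaling = 13L, mode = mode, pcls = pcls)
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the modified algorithm: SBX crossover with polynomial
#' order 10 applied with probability 0.9 and 0.5 genewise swap, Cauchy
#' mutation along a random direction with half-width-at-half-maximum 0.18
#' (in baseline-normalized units) applied with probability 0.9, tournament
#' selection, an elite fraction of 6.6%, and 9 stimulations per fitness
#' evaluation (odd, to expose 1:1 alternans across generations).
#'
#' @param population population size.
#' @param generations generation budget.
#' @param p_crossover,p_mutation per-organism operator probabilities.
#' @param eta SBX polynomial order.
#' @param swap_p SBX genewise swap probability.
#' @param gamma Cauchy mutation HWHM (baseline-normalized units).
#' @param elite_fraction fraction of the population copied unmodified into
#'   the next generation (replacing the worst offspring).
#' @param n_beats stimulations per evaluation before the fitness beat (odd).
#' @param mode forward model: `"cell"`, `"cable"` or `"toy"`.
#' @param mutation_op `"vector"` (whole-genome Cauchy step along a random
#'   direction) or `"point"` (per-gene Cauchy with a fixed probability, kept
#'   for comparison experiments).
#' @param point_p per-gene probability for `"point"` mutation.
#' @param cable a [cable_config()] for `mode = "cable"`.
#' @param penalty fitness assigned to discarded organisms (mV).
#' @param dt_max integrator step cap (ms).
#' @param stim stimulus `list(amplitude =, duration =)`.
#' @param fitness_threshold optional early-stop fitness (mV).
#' @return list of class `"ga_config"`.
#' @export
ga_config <- function(population = 100, generations = 100,
                      p_crossover = 0.9, p_mutation = 0.9, eta = 10,
                      swap_p = 0.5, gamma = 0.18, elite_fraction = 0.066,
                      n_beats = 9, mode = c("cell", "cable", "toy"),
                      mutation_op = c("vector", "point"), point_p = 0.1,
                      cable = NULL, penalty = 1000, dt_max = 1,
                      stim = default_stim(), fitness_threshold = 0) {
  mode <- match.arg(mode)
  mutation_op <- match.arg(mutation_op)
  stopifnot(population >= 2, generations >= 1,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1,
            elite_fraction >= 0, elite_fraction < 1,
            n_beats >= 1)
  if (n_beats %% 2 == 0)
    warning("even n_beats cannot expose 1:1 alternans across generations")
  if (mode == "cable" && is.null(cable)) cable <- cable_config()
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 eta = eta, swap_p = swap_p, gamma = gamma,
                 elite_fraction = elite_fraction, n_beats = as.integer(n_beats),
                 mode = mode, mutation_op = mutation_op, point_p = point_p,
                 cable = cable, penalty = penalty, dt_max = dt_max,
                 stim = stim, fitness_threshold = fitness_threshold),
            class = "ga_config")
}

new_organism <- function(genome, states, fitness = Inf, per_pcl = NULL) {
  list(genome = genome, states = states, fitness = fitness, per_pcl = per_pcl)
}

init_states <- function(spec, config, genome) {
  if (spec$mode == "toy") return(NULL)
  lapply(spec$pcls, function(pcl) {
    st <- ord_initial_state()
    if (spec$mode == "cable")
      matrix(st, nrow = config$cable$n_cells, ncol = 41, byrow = TRUE,
             dimnames = list(NULL, names(st)))
    else st
  })
}

#' Initialize a random population
#'
#' Scaling multipliers are drawn log-uniformly on \[0.01, 4\] (the search
#' spans two orders of magnitude below baseline and a factor 4 above, so a
#' log-uniform prior treats fold changes symmetrically); slow-variable genes
#' uniformly within their physiological bounds. Persisted states start from
#' the published resting steady state.
#'
#' @param config a [ga_config()].
#' @param spec a [genome_spec()].
#' @return list of organisms.
#' @export
init_population <- function(config, spec) {
  lapply(seq_len(config$population), function(i) {
    g <- numeric(length(spec$names))
    names(g) <- spec$names
    ns <- spec$n_scaling
    g[seq_len(ns)] <- exp(runif(ns, log(spec$lower[seq_len(ns)]),
                                log(spec$upper[seq_len(ns)])))
    if (length(g) > ns) {
      idx <- seq.int(ns + 1, length(g))
      g[idx] <- runif(length(idx), spec$lower[idx], spec$upper[idx])
    }
    new_organism(g, init_states(spec, config, g))
  })
}

# write the slow-variable genes into a persisted state (single cell or cable
# matrix). Subspace Na tracks [Na+]i; junctional SR Ca is rescaled with NSR
# Ca to avoid an unphysical discontinuity between the SR compartments.
write_slow_genes <- function(state, nai, cansr) {
  scale1 <- function(st) {
    ratio <- cansr / st[["cansr"]]
    st[["nai"]] <- nai
    st[["nass"]] <- nai
    st[["cajsr"]] <- st[["cajsr"]] * ratio
    st[["cansr"]] <- cansr
    st
  }
  if (is.matrix(state)) t(apply(state, 1, scale1)) else scale1(state)
}

#' Evaluate one organism against the baseline set
#'
#' For each PCL: the persisted state is restored, the slow-variable genes
#' overwrite `[Na+]i` and `[Ca2+]NSR`, the model is paced for
#' `config$n_beats` beats, the fitness beat is the last one, the final state
#' is persisted, and the reached slow concentrations are written back into
#' the genome (so mutation explores around the trajectory while selection
#' discards non-steady solutions). Integration failures yield the penalty
#' fitness; the organism survives.
#'
#' @param organism an organism (see [init_population()]).
#' @param baselines a [baseline_set()].
#' @param config a [ga_config()].
#' @param spec a [genome_spec()].
#' @return the organism with `fitness`, `per_pcl`, updated `states` and
#'   (slow genes) `genome`.
#' @export
evaluate_organism <- function(organism, baselines, config, spec) {
  if (spec$mode == "toy") {
    cands <- lapply(spec$pcls, function(pcl)
      toy_ap(toy_reference() * organism$genome, pcl))
    fit <- ap_fitness(baselines, cands, penalty = config$penalty)
    organism$fitness <- fit$total
    organism$per_pcl <- fit$per_pcl
    return(organism)
  }
  scal <- organism$genome[seq_len(13)]
  cands <- vector("list", length(spec$pcls))
  for (i in seq_along(spec$pcls)) {
    pcl <- spec$pcls[i]
    nai_g <- organism$genome[[paste0("nai_", pcl)]]
    cansr_g <- organism$genome[[paste0("cansr_", pcl)]]
    st <- write_slow_genes(organism$states[[i]], nai_g, cansr_g)
    if (spec$mode == "cable") {
      res <- simulate_cable(config$cable, scal, pcl, n_beats = config$n_beats,
                            states = st, stim = config$stim,
                            dt_max = config$dt_max)
      organism$states[[i]] <- res$final_states
      final1 <- res$final_states[config$cable$record_cell, ]
    } else {
      res <- pace_cell_beats(st, scal, pcl, config$n_beats, config$stim,
                             config$dt_max)
      organism$states[[i]] <- res$final_state
      final1 <- res$final_state
    }
    cands[i] <- list(if (res$ok) res$trace else NULL)
    if (all(is.finite(final1)) && final1[["nai"]] > 0 && final1[["cansr"]] > 0) {
      organism$genome[[paste0("nai_", pcl)]] <-
        clamp(final1[["nai"]], 1, 20)
      organism$genome[[paste0("cansr_", pcl)]] <-
        clamp(final1[["cansr"]], 0.3, 6)
    }
  }
  fit <- ap_fitness(baselines, cands, penalty = config$penalty)
  organism$fitness <- fit$total
  organism$per_pcl <- fit$per_pcl
  organism
}

pace_cell_beats <- function(state, scaling, pcl, n_beats, stim, dt_max) {
  res <- integrate_cell(state, scaling, duration = n_beats * pcl,
                        stim_times = (seq_len(n_beats) - 1) * pcl,
                        stim_amplitude = stim$amplitude,
                        stim_duration = stim$duration,
                        dt_max = dt_max,
                        record_from = (n_beats - 1) * pcl, pcl = pcl)
  if (res$ok) {
    tr <- res$trace
    t0 <- (n_beats - 1) * pcl
    res$trace <- ap_trace(tr$time - t0, tr$v, pcl = pcl)
  }
  res
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Tournament selection
#'
#' Two shuffled copies of the population are paired position by position;
#' the lower-RMSE member of each pair enters the mating pool, which has the
#' population size.
#'
#' @param population evaluated organisms.
#' @return list of organisms (the mating pool).
#' @export
tournament_select <- function(population) {
  n <- length(population)
  i1 <- sample.int(n)
  i2 <- sample.int(n)
  f <- vapply(population, function(o) o$fitness, numeric(1))
  win <- ifelse(f[i1] <= f[i2], i1, i2)
  population[win]
}

#' SBX spread factors
#'
#' Draws from the simulated-binary-crossover spread distribution with
#' polynomial order `eta` by inverse CDF: `(2u)^(1/(eta+1))` for `u <= 1/2`,
#' `(2(1-u))^(-1/(eta+1))` otherwise.
#'
#' @param n number of draws.
#' @param eta polynomial order.
#' @return numeric vector of spread factors (>= 0).
#' @export
sbx_spread <- function(n, eta) {
  u <- runif(n)
  ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)), (2 * (1 - u))^(-1 / (eta + 1)))
}

#' Simulated binary crossover of two genomes
#'
#' Children are symmetric about the parents' mean with a per-gene spread
#' factor from the order-`eta` polynomial distribution; after crossover each
#' gene pair is swapped between the children with probability `swap_p`.
#' Results are clipped to the per-gene bounds.
#'
#' @param g1,g2 parent genomes (equal length).
#' @param eta SBX polynomial order.
#' @param swap_p genewise swap probability.
#' @param spec a [genome_spec()] providing bounds.
#' @return list of two child genomes.
#' @export
sbx_crossover <- function(g1, g2, eta = 10, swap_p = 0.5, spec) {
  stopifnot(length(g1) == length(g2))
  k <- length(g1)
  beta <- sbx_spread(k, eta)
  c1 <- 0.5 * ((1 + beta) * g1 + (1 - beta) * g2)
  c2 <- 0.5 * ((1 - beta) * g1 + (1 + beta) * g2)
  swap <- runif(k) < swap_p
  tmp <- c1[swap]; c1[swap] <- c2[swap]; c2[swap] <- tmp
  list(clamp(c1, spec$lower, spec$upper), clamp(c2, spec$lower, spec$upper))
}

#' Cauchy mutation along a random direction in parameter space
#'
#' A direction is drawn uniformly on the unit sphere in baseline-normalized
#' gene space and the whole genome moves along it by a signed step drawn
#' from a Cauchy distribution with half-width-at-half-maximum `gamma`,
#' truncated so that every gene stays within its bounds (the truncation is
#' the normalization of the heavy-tailed density to the admissible range).
#' All genes move simultaneously, unlike per-gene point mutation.
#'
#' @param genome named genome vector.
#' @param gamma Cauchy HWHM in normalized units.
#' @param spec a [genome_spec()].
#' @return mutated genome.
#' @export
cauchy_vector_mutation <- function(genome, gamma = 0.18, spec) {
  z <- genome / spec$base
  lo <- spec$lower / spec$base
  hi <- spec$upper / spec$base
  u <- rnorm(length(z))
  u <- u / sqrt(sum(u^2))
  # admissible signed step range along u
  r_hi <- Inf; r_lo <- -Inf
  pos <- u > 1e-12; neg <- u < -1e-12
  if (any(pos)) {
    r_hi <- min(r_hi, min((hi[pos] - z[pos]) / u[pos]))
    r_lo <- max(r_lo, max((lo[pos] - z[pos]) / u[pos]))
  }
  if (any(neg)) {
    r_hi <- min(r_hi, min((lo[neg] - z[neg]) / u[neg]))
    r_lo <- max(r_lo, max((hi[neg] - z[neg]) / u[neg]))
  }
  if (!is.finite(r_hi)) r_hi <- 0
  if (!is.finite(r_lo)) r_lo <- 0
  r <- rcauchy_trunc(1, gamma, r_lo, r_hi)
  clamp((z + r * u) * spec$base, spec$lower, spec$upper)
}

# truncated Cauchy(0, gamma) on [lo, hi] by inverse CDF
rcauchy_trunc <- function(n, gamma, lo, hi) {
  p_lo <- atan(lo / gamma) / pi + 0.5
  p_hi <- atan(hi / gamma) / pi + 0.5
  p <- runif(n, p_lo, p_hi)
  gamma * tan(pi * (p - 0.5))
}

#' Per-gene point mutation (comparison operator)
#'
#' Mutates each gene independently with probability `point_p` by a
#' truncated Cauchy step with HWHM `gamma` in normalized units. Kept to
#' reproduce the comparison between whole-vector and per-gene mutation.
#'
#' @inheritParams cauchy_vector_mutation
#' @param point_p per-gene mutation probability.
#' @return mutated genome.
#' @export
cauchy_point_mutation <- function(genome, gamma = 0.18, point_p = 0.1, spec) {
  z <- genome / spec$base
  lo <- spec$lower / spec$base
  hi <- spec$upper / spec$base
  hit <- runif(length(z)) < point_p
  for (i in which(hit))
    z[i] <- z[i] + rcauchy_trunc(1, gamma, lo[i] - z[i], hi[i] - z[i])
  clamp(z * spec$base, spec$lower, spec$upper)
}

#' Elite replacement
#'
#' The top `n_elite` organisms of the previous generation (unspoiled
#' genomes, but carrying their latest persisted states) replace the worst
#' offspring.
#'
#' @param elites list of elite organisms (already evaluated).
#' @param offspring evaluated offspring population.
#' @return next-generation population.
#' @export
elitism_replace <- function(elites, offspring) {
  if (!length(elites)) return(offspring)
  if (length(elites) >= length(offspring))
    stop("elite count must be smaller than the population")
  f <- vapply(offspring, function(o) o$fitness, numeric(1))
  worst <- order(f, decreasing = TRUE)[seq_along(elites)]
  offspring[worst] <- elites
  offspring
}

#' Run the modified genetic algorithm
#'
#' Generational loop: evaluate, save elite copies, tournament selection,
#' SBX crossover (children inherit the persisted states of their respective
#' parents), Cauchy mutation, evaluation of the offspring, and elite
#' replacement. Deterministic given the R random seed set by the caller.
#'
#' @param config a [ga_config()].
#' @param baselines a [baseline_set()].
#' @param snapshot_at generations at which to store the population's scaling
#'   multipliers (matrix snapshots for PCA diagnostics).
#' @param verbose print per-generation progress.
#' @return list: `best` organism, `history` data.frame (generation, best
#'   and mean fitness), `population` (final), `snapshots` (named list of
#'   organisms-by-multipliers matrices), `spec`.
#' @export
run_ga <- function(config, baselines, snapshot_at = integer(), verbose = FALSE) {
  spec <- genome_spec(config$mode, baselines$pcls)
  n_elite <- floor(config$elite_fraction * config$population)
  pop <- init_population(config, spec)
  pop <- lapply(pop, evaluate_organism, baselines = baselines,
                config = config, spec = spec)
  history <- data.frame(generation = integer(), best = numeric(),
                        mean = numeric())
  snapshots <- list()
  take_snapshot <- function(gen, pop) {
    m <- t(vapply(pop, function(o) o$genome[seq_len(spec$n_scaling)],
                  numeric(spec$n_scaling)))
    colnames(m) <- spec$names[seq_len(spec$n_scaling)]
    m
  }
  best <- NULL
  for (gen in seq_len(config$generations)) {
    f <- vapply(pop, function(o) o$fitness, numeric(1))
    if (all(f >= config$penalty))
      warning("generation ", gen, ": all organisms penalized", call. = FALSE)
    ord <- order(f)
    # the reported solution is the best organism of the latest generation:
    # persisted states drift, so an old low score is not comparable
    best <- pop[[ord[1]]]
    history <- rbind(history, data.frame(generation = gen, best = f[ord[1]],
                                         mean = mean(f)))
    if (gen %in% snapshot_at)
      snapshots[[as.character(gen)]] <- take_snapshot(gen, pop)
    if (verbose)
      message(sprintf("gen %4d  best %.4g  mean %.4g", gen, f[ord[1]], mean(f)))
    if (f[ord[1]] <= config$fitness_threshold || gen == config$generations)
      break
    elites <- pop[ord[seq_len(n_elite)]]
    pool <- tournament_select(pop)
    offspring <- vector("list", config$population)
    i <- 1
    while (i <= config$population) {
      if (i < config$population) {
        a <- pool[[i]]; b <- pool[[i + 1]]
        if (runif(1) < config$p_crossover) {
          ch <- sbx_crossover(a$genome, b$genome, config$eta, config$swap_p,
                              spec)
          a$genome <- ch[[1]]; b$genome <- ch[[2]]
        }
        offspring[[i]] <- a; offspring[[i + 1]] <- b
        i <- i + 2
      } else {
        offspring[[i]] <- pool[[i]]
        i <- i + 1
      }
    }
    offspring <- lapply(offspring, function(o) {
      if (runif(1) < config$p_mutation) {
        o$genome <- if (config$mutation_op == "vector")
          cauchy_vector_mutation(o$genome, config$gamma, spec)
        else
          cauchy_point_mutation(o$genome, config$gamma, config$point_p, spec)
      }
      o
    })
    offspring <- lapply(offspring, evaluate_organism, baselines = baselines,
                        config = config, spec = spec)
    # elite copies keep their genomes unmodified but are re-simulated like
    # every other organism: their persisted states keep approaching steady
    # state and their RMSE moves with them (a stale score would let a
    # non-steady elite shield its slot indefinitely)
    elites <- lapply(elites, evaluate_organism, baselines = baselines,
                     config = config, spec = spec)
    pop <- elitism_replace(elites, offspring)
  }
  list(best = best, history = history, population = pop,
       snapshots = snapshots, spec = spec)
}
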