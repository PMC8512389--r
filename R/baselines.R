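# Swarm-intelligence comparators. The published experiments fix only the
# hyperparameters (threshold/crossover/mutation for GA; threshold/inertia/
# acceleration for BPSO; ants/pheromone/deposit/evaporation for ACO); the
# algorithm bodies here are deliberately minimal textbook variants:
# tournament GA with elitism, global-best BPSO with a sigmoid transfer, and
# a pheromone-ratio ACO. All share the memoized objective and the
# fewer-features tie-break of better().

#' Genetic-algorithm configuration
#'
#' @param pop_size population size.
#' @param threshold decode threshold: gene >= threshold selects the feature.
#' @param crossover_rate per-pair probability of uniform crossover.
#' @param mutation_rate per-gene probability of resampling the gene.
#' @param generations number of generations.
#' @param eval_budget optional cap on classifier evaluations.
#' @param seed integer seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 20L, threshold = 0.5, crossover_rate = 0.8,
                      mutation_rate = 0.01, generations = 50L,
                      eval_budget = Inf, seed = 1L) {
  stop_if_not(is_count(pop_size, 2L), "pop_size must be >= 2")
  stop_if_not(crossover_rate >= 0 && crossover_rate <= 1 &&
                mutation_rate >= 0 && mutation_rate <= 1, "rates must lie in [0, 1]")
  structure(list(pop_size = as.integer(pop_size), threshold = threshold,
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 generations = as.integer(generations), eval_budget = eval_budget,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Decode a real-coded genome to a feature mask
#'
#' @param genome numeric vector in `[0, 1]^N`.
#' @param threshold decode threshold; `genome >= threshold` selects.
#' @return Integer 0/1 mask (an empty decode is repaired by selecting the
#'   largest gene).
#' @export
decode_genome <- function(genome, threshold = 0.5) {
  m <- as.integer(genome >= threshold)
  if (!any(m == 1L)) m[which.max(genome)] <- 1L
  m
}

#' Genetic-algorithm feature-subset search
#'
#' Real-coded genomes in `[0, 1]^N` decoded by the threshold; binary
#' tournament selection (size 2), uniform crossover, per-gene mutation by
#' resampling, elitism of one. Deterministic under the config seed.
#'
#' @param objective a [mask_objective()] or [function_objective()].
#' @param config a [ga_config()].
#' @return An object of class `fs_run` (method `"ga"`).
#' @export
run_ga <- function(objective, config = ga_config()) {
  stop_if_not(inherits(objective, "mask_objective"), "objective must be a mask_objective")
  n <- objective$n_features
  t0 <- proc.time()[["elapsed"]]
  local_seed(config$seed, {
    pop <- matrix(stats::runif(config$pop_size * n), config$pop_size, n)
    score <- function(g) objective$evaluate(decode_genome(g, config$threshold))
    fits <- lapply(seq_len(config$pop_size), function(i) score(pop[i, ]))
    best_ix <- which_best(fits)
    best <- decode_genome(pop[best_ix, ], config$threshold)
    best_fit <- fits[[best_ix]]
    hist <- vector("list", config$generations)
    for (gen in seq_len(config$generations)) {
      if (objective$n_evals() >= config$eval_budget) break
      newpop <- matrix(0, config$pop_size, n)
      newpop[1, ] <- pop[best_ix, ]             # elitism of 1
      for (j in seq(2L, config$pop_size)) {
        p1 <- tournament(fits)
        p2 <- tournament(fits)
        child <- pop[p1, ]
        if (stats::runif(1) < config$crossover_rate) {
          take2 <- stats::runif(n) < 0.5
          child[take2] <- pop[p2, take2]
        }
        mut <- stats::runif(n) < config$mutation_rate
        child[mut] <- stats::runif(sum(mut))
        newpop[j, ] <- child
      }
      pop <- newpop
      fits <- lapply(seq_len(config$pop_size), function(i) score(pop[i, ]))
      gen_ix <- which_best(fits)
      if (better(fits[[gen_ix]], best_fit)) {
        best_fit <- fits[[gen_ix]]
        best <- decode_genome(pop[gen_ix, ], config$threshold)
      }
      best_ix <- gen_ix
      hist[[gen]] <- data.frame(iteration = gen, n_evaluations = objective$n_evals(),
                                best_fitness = best_fit$accuracy,
                                n_selected = best_fit$n_selected,
                                elapsed_s = proc.time()[["elapsed"]] - t0)
    }
    history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    new_fs_run("ga", best, best_fit, history, config, objective)
  })
}

which_best <- function(fits) {
  ix <- 1L
  for (j in seq_along(fits)[-1L]) if (better(fits[[j]], fits[[ix]])) ix <- j
  ix
}

tournament <- function(fits, size = 2L) {
  cand <- sample.int(length(fits), size)
  cand[which_best(fits[cand])]
}

#' Binary particle-swarm configuration
#'
#' @param swarm_size number of particles.
#' @param threshold transfer threshold: a bit is selected iff
#'   `sigmoid(velocity) >= threshold` (the boundary `sigmoid(0) = 0.5`
#'   resolves as "select").
#' @param inertia inertia weight.
#' @param c1,c2 cognitive and social acceleration factors.
#' @param v_max symmetric velocity clamp.
#' @param iterations number of iterations.
#' @param eval_budget optional cap on classifier evaluations.
#' @param seed integer seed.
#' @return An object of class `bpso_config`.
#' @export
bpso_config <- function(swarm_size = 20L, threshold = 0.5, inertia = 0.9,
                        c1 = 2, c2 = 2, v_max = 4, iterations = 50L,
                        eval_budget = Inf, seed = 1L) {
  stop_if_not(inertia > 0 && inertia <= 1, "inertia must lie in (0, 1]")
  structure(list(swarm_size = as.integer(swarm_size), threshold = threshold,
                 inertia = inertia, c1 = c1, c2 = c2, v_max = v_max,
                 iterations = as.integer(iterations), eval_budget = eval_budget,
                 seed = as.integer(seed)),
            class = "bpso_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binary particle-swarm feature-subset search
#'
#' Global-best topology: each particle's velocity is updated with inertia
#' plus cognitive and social pulls toward its personal best and the swarm
#' best, clamped to `[-v_max, v_max]`, and its position is re-derived
#' through the sigmoid transfer against the threshold. Empty positions are
#' repaired by selecting the bit with the largest transfer value.
#'
#' @param objective a [mask_objective()] or [function_objective()].
#' @param config a [bpso_config()].
#' @return An object of class `fs_run` (method `"bpso"`).
#' @export
run_bpso <- function(objective, config = bpso_config()) {
  stop_if_not(inherits(objective, "mask_objective"), "objective must be a mask_objective")
  n <- objective$n_features
  t0 <- proc.time()[["elapsed"]]
  local_seed(config$seed, {
    S <- config$swarm_size
    V <- matrix(stats::runif(S * n, -config$v_max, config$v_max), S, n)
    decode_v <- function(v) {
      m <- as.integer(sigmoid(v) >= config$threshold)
      if (!any(m == 1L)) m[which.max(sigmoid(v))] <- 1L
      m
    }
    X <- t(apply(V, 1, decode_v))
    fits <- lapply(seq_len(S), function(i) objective$evaluate(X[i, ]))
    pbest <- X; pfits <- fits
    g_ix <- which_best(fits)
    gbest <- X[g_ix, ]; gfit <- fits[[g_ix]]
    hist <- vector("list", config$iterations)
    for (iter in seq_len(config$iterations)) {
      if (objective$n_evals() >= config$eval_budget) break
      r1 <- matrix(stats::runif(S * n), S, n)
      r2 <- matrix(stats::runif(S * n), S, n)
      V <- config$inertia * V +
        config$c1 * r1 * (pbest - X) +
        config$c2 * r2 * (matrix(gbest, S, n, byrow = TRUE) - X)
      V <- pmin(pmax(V, -config$v_max), config$v_max)
      X <- t(apply(V, 1, decode_v))
      for (i in seq_len(S)) {
        f <- objective$evaluate(X[i, ])
        if (better(f, pfits[[i]])) { pbest[i, ] <- X[i, ]; pfits[[i]] <- f }
        if (better(f, gfit)) { gbest <- X[i, ]; gfit <- f }
      }
      hist[[iter]] <- data.frame(iteration = iter, n_evaluations = objective$n_evals(),
                                 best_fitness = gfit$accuracy,
                                 n_selected = gfit$n_selected,
                                 elapsed_s = proc.time()[["elapsed"]] - t0)
    }
    history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    new_fs_run("bpso", as.integer(gbest), gfit, history, config, objective)
  })
}

#' Ant-colony configuration
#'
#' @param n_ants number of ants per iteration.
#' @param tau0 initial pheromone per feature.
#' @param deposit pheromone added to each feature of the iteration-best ant.
#' @param retention fraction of pheromone retained per iteration (the
#'   published "evaporation rate 0.95" read as retention).
#' @param iterations number of iterations.
#' @param eval_budget optional cap on classifier evaluations.
#' @param seed integer seed.
#' @return An object of class `aco_config`.
#' @export
aco_config <- function(n_ants = 10L, tau0 = 1, deposit = 0.1, retention = 0.95,
                       iterations = 50L, eval_budget = Inf, seed = 1L) {
  stop_if_not(tau0 > 0 && deposit > 0, "pheromones must be positive")
  stop_if_not(retention > 0 && retention <= 1, "retention must lie in (0, 1]")
  structure(list(n_ants = as.integer(n_ants), tau0 = tau0, deposit = deposit,
                 retention = retention, iterations = as.integer(iterations),
                 eval_budget = eval_budget, seed = as.integer(seed)),
            class = "aco_config")
}

# inclusion probability of each feature given pheromones tau
aco_inclusion_prob <- function(tau) tau / (tau + mean(tau))

#' Ant-colony feature-subset search
#'
#' Each feature carries a pheromone; an ant includes feature `j` with
#' probability `tau_j / (tau_j + mean(tau))`, so equal pheromones give every
#' feature a coin flip. After each iteration all pheromones are multiplied
#' by the retention factor and the iteration-best ant deposits on its
#' selected features.
#'
#' @param objective a [mask_objective()] or [function_objective()].
#' @param config an [aco_config()].
#' @return An object of class `fs_run` (method `"aco"`) whose result also
#'   carries the final `pheromone` vector.
#' @export
run_aco <- function(objective, config = aco_config()) {
  stop_if_not(inherits(objective, "mask_objective"), "objective must be a mask_objective")
  n <- objective$n_features
  t0 <- proc.time()[["elapsed"]]
  local_seed(config$seed, {
    tau <- rep(config$tau0, n)
    best <- NULL; best_fit <- NULL
    hist <- vector("list", config$iterations)
    for (iter in seq_len(config$iterations)) {
      if (objective$n_evals() >= config$eval_budget) break
      iter_best <- NULL; iter_fit <- NULL
      for (a in seq_len(config$n_ants)) {
        p <- aco_inclusion_prob(tau)
        m <- repair_mask(as.integer(stats::runif(n) < p))
        f <- objective$evaluate(m)
        if (is.null(iter_fit) || better(f, iter_fit)) { iter_best <- m; iter_fit <- f }
      }
      tau <- tau * config$retention
      tau[iter_best == 1L] <- tau[iter_best == 1L] + config$deposit
      if (is.null(best_fit) || better(iter_fit, best_fit)) {
        best <- iter_best; best_fit <- iter_fit
      }
      hist[[iter]] <- data.frame(iteration = iter, n_evaluations = objective$n_evals(),
                                 best_fitness = best_fit$accuracy,
                                 n_selected = best_fit$n_selected,
                                 elapsed_s = proc.time()[["elapsed"]] - t0)
    }
    history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    run <- new_fs_run("aco", best, best_fit, history, config, objective)
    run$pheromone <- tau
    run
  })
}
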