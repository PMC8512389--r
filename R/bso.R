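#' Bee-swarm search configuration
#'
#' Defaults follow the published reference settings: 10 bees, `flip = 5`,
#' `max_chances = 3`. The local-search mode selects what each bee runs in
#' its assigned region: `"deep-q"` (the hybrid's multi-agent DQN),
#' `"tabular-q"` (lookup-table Q-learning, the QBSO-style comparison mode)
#' or `"hill"` (best-improvement hill climbing over single-bit flips, the
#' plain-BSO mode).
#'
#' @param nb number of bees.
#' @param flip spacing parameter of the search-region generator; must not
#'   exceed the mask length. Spawned solutions sit at a Hamming distance
#'   inversely proportional to `flip` from the reference solution.
#' @param max_chances non-improving iterations tolerated before the search
#'   diversifies to a distant reference solution.
#' @param max_iter outer iterations.
#' @param local_search local-search mode, see above.
#' @param local_budget per-bee local-search budget: agent steps for the
#'   Q-modes, candidate evaluations for hill climbing.
#' @param eval_budget optional cap on total classifier evaluations; the run
#'   stops once the objective has spent it (used for budget-matched
#'   algorithm comparisons).
#' @param seed integer seed; the whole run is a deterministic function of it.
#' @param qlearn a [qlearn_params()] for the Q-modes (its `mode` field is
#'   overridden to match `local_search`).
#' @param reward a [reward_params()].
#' @return An object of class `bso_config`.
#' @export
bso_config <- function(nb = 10L, flip = 5L, max_chances = 3L, max_iter = 50L,
                       local_search = c("deep-q", "tabular-q", "hill"),
                       local_budget = 30L, eval_budget = Inf, seed = 1L,
                       qlearn = qlearn_params(), reward = reward_params()) {
  local_search <- match.arg(local_search)
  stop_if_not(is_count(nb, 1L), "nb must be >= 1")
  stop_if_not(is_count(flip, 1L), "flip must be >= 1")
  stop_if_not(is_count(max_chances, 1L), "max_chances must be >= 1")
  stop_if_not(is_count(max_iter, 1L), "max_iter must be >= 1")
  stop_if_not(is_count(local_budget, 0L), "local_budget must be >= 0")
  if (local_search == "tabular-q") qlearn$mode <- "tabular"
  if (local_search == "deep-q") qlearn$mode <- "deep"
  structure(list(nb = as.integer(nb), flip = as.integer(flip),
                 max_chances = as.integer(max_chances),
                 max_iter = as.integer(max_iter), local_search = local_search,
                 local_budget = as.integer(local_budget),
                 eval_budget = eval_budget, seed = as.integer(seed),
                 qlearn = qlearn, reward = reward),
            class = "bso_config")
}

# positions (1-based) flipped by strategy-1 mask i (0-based) for given N, flip
strategy1_positions <- function(i, n, flip) seq.int(i + 1L, n, by = flip)

#' Generate a bee-swarm search region
#'
#' Derives `nb` candidate masks from a reference solution by three flip
#' strategies. Strategy 1 (first `min(flip, nb)` masks): mask `i` flips the
#' bits at 0-based positions `i, i + flip, i + 2 flip, ...`. Strategy 2
#' (next masks): mask `k` flips the contiguous block of `ceiling(N / flip)`
#' bits starting at 0-based position `k * ceiling(N / flip)`. Strategy 3
#' (remainder): each mask flips `ceiling(N / flip)` distinct random
#' positions. Any all-zero result is repaired by setting one random bit,
#' and any duplicate of the reference or of an earlier candidate is
#' re-randomized, so the region always holds `nb` masks at Hamming
#' distance >= 1 from the reference.
#'
#' @param ref 0/1 reference mask of length N.
#' @param config a [bso_config()] (uses `nb` and `flip`; `flip` must be <= N).
#' @return List of `nb` integer masks.
#' @examples
#' cfg <- bso_config(nb = 10, flip = 4)
#' region <- generate_search_region(rep(0L, 16), cfg)
#' which(region[[1]] == 1L) - 1L   # 0 4 8 12
#' @export
generate_search_region <- function(ref, config) {
  ref <- as_mask(ref)
  n <- length(ref)
  nb <- config$nb; flip <- config$flip
  stop_if_not(flip <= n, "flip (%d) must not exceed the mask length (%d)", flip, n)
  h <- as.integer(ceiling(n / flip))
  masks <- vector("list", nb)
  made <- 0L
  n1 <- min(flip, nb)
  for (i in seq_len(n1) - 1L) {
    m <- ref
    pos <- strategy1_positions(i, n, flip)
    m[pos] <- 1L - m[pos]
    made <- made + 1L
    masks[[made]] <- m
  }
  k <- 0L
  while (made < nb && k * h < n) {
    pos <- (k * h + 1L):min((k + 1L) * h, n)
    m <- ref
    m[pos] <- 1L - m[pos]
    made <- made + 1L
    masks[[made]] <- m
    k <- k + 1L
  }
  while (made < nb) {
    pos <- sample.int(n, min(h, n))
    m <- ref
    m[pos] <- 1L - m[pos]
    made <- made + 1L
    masks[[made]] <- m
  }
  # repair empties; re-randomize duplicates of ref or earlier candidates
  seen <- new.env(parent = emptyenv())
  seen[[mask_key(ref)]] <- TRUE
  for (j in seq_len(nb)) {
    m <- repair_mask(masks[[j]])
    tries <- 0L
    while (!is.null(seen[[mask_key(m)]]) && tries < 100L) {
      pos <- sample.int(n, min(h, n))
      m <- ref
      m[pos] <- 1L - m[pos]
      m <- repair_mask(m)
      tries <- tries + 1L
    }
    seen[[mask_key(m)]] <- TRUE
    masks[[j]] <- m
  }
  masks
}

#' Best-improvement hill climbing over single-bit flips
#'
#' The plain-BSO local search: from `start`, repeatedly evaluate every
#' single-bit-flip neighbor (never the all-zero mask), move to the best one
#' if it improves on the incumbent by [better()], and stop at a local
#' optimum or when the evaluation budget is spent. The result is never worse
#' than the start, and the fitness sequence along accepted moves is strictly
#' increasing.
#'
#' @param start 0/1 starting mask.
#' @param objective a [mask_objective()] or [function_objective()].
#' @param budget maximum number of neighbor evaluations (>= 0; 0 returns
#'   the evaluated start).
#' @return List with `mask`, `fitness`, and `trace` (fitness after each
#'   accepted move, starting value included).
#' @export
hill_climb_local_search <- function(start, objective, budget) {
  stop_if_not(is_count(budget, 0L), "budget must be >= 0")
  cur <- as_mask(start)
  fit <- objective$evaluate(cur)
  trace <- fit$accuracy
  spent <- 0L
  repeat {
    if (spent >= budget) break
    best_nb <- NULL; best_fit <- fit
    for (u in sample.int(length(cur))) {     # scan order randomized, choice is best-of
      if (spent >= budget) break
      cand <- cur; cand[u] <- 1L - cand[u]
      if (!any(cand == 1L)) next
      f <- objective$evaluate(cand)
      spent <- spent + 1L
      if (better(f, best_fit)) { best_nb <- cand; best_fit <- f }
    }
    if (is.null(best_nb)) break
    cur <- best_nb; fit <- best_fit
    trace <- c(trace, fit$accuracy)
  }
  list(mask = cur, fitness = fit, trace = trace)
}

in_tabu <- function(mask, tabu) any(vapply(tabu, function(t) identical(t, mask), logical(1)))

#' Select the next reference solution
#'
#' The intensification / diversification step run once per iteration after
#' all bees have danced. The iteration's best dance entry becomes `best_sol`.
#' If it beats the best global solution, the search intensifies there and
#' the chance counter resets; otherwise a remaining chance is spent and the
#' search still intensifies on `best_sol`; with no chances left it
#' diversifies to the generated candidate farthest (by Hamming distance)
#' from the best global solution among candidates not in the tabu list.
#' A reference solution never repeats within a run: choices already in the
#' tabu list are passed over, falling back to diversification and finally
#' to a random mask. The new reference is appended to the tabu list.
#'
#' @param state list with `best_global`, `best_global_fit`, `dance` (list of
#'   `list(mask, fitness)`), `candidates` (this iteration's region),
#'   `tabu` (list of masks), `n_chances`.
#' @param config a [bso_config()].
#' @return The updated state (fields `ref`, `best_global`, `best_global_fit`,
#'   `tabu`, `n_chances`, `event` one of improve/intensify/diversify).
#' @export
advance_reference <- function(state, config) {
  stop_if_not(length(state$dance) >= 1, "dance table is empty")
  best_ix <- 1L
  for (j in seq_along(state$dance)[-1L]) {
    if (better(state$dance[[j]]$fitness, state$dance[[best_ix]]$fitness)) best_ix <- j
  }
  best_sol <- state$dance[[best_ix]]$mask
  best_fit <- state$dance[[best_ix]]$fitness

  improved <- better(best_fit, state$best_global_fit)
  if (improved) {
    state$best_global <- best_sol
    state$best_global_fit <- best_fit
  }

  pick_dance <- function() {
    # best non-tabu dance entry, or NULL
    ord <- order(vapply(state$dance, function(d) -d$fitness$accuracy, numeric(1)),
                 vapply(state$dance, function(d) d$fitness$n_selected, integer(1)))
    for (j in ord) if (!in_tabu(state$dance[[j]]$mask, state$tabu))
      return(state$dance[[j]]$mask)
    NULL
  }
  diversify <- function() {
    cand <- Filter(function(m) !in_tabu(m, state$tabu), state$candidates)
    if (length(cand) == 0) return(random_mask(length(state$best_global)))
    d <- vapply(cand, function(m) hamming(m, state$best_global), integer(1))
    cand[[which.max(d)]]
  }

  # the chance counter records remaining attempts around the current region:
  # each non-improving iteration spends one, and the search escapes on the
  # iteration that spends the last
  if (!improved) state$n_chances <- state$n_chances - 1L
  else state$n_chances <- config$max_chances
  if (improved || state$n_chances > 0L) {
    new_ref <- if (!in_tabu(best_sol, state$tabu)) best_sol else pick_dance()
    state$event <- if (improved) "improve" else "intensify"
    if (is.null(new_ref)) {             # every dance entry already visited
      new_ref <- diversify()
      state$n_chances <- config$max_chances
      state$event <- "diversify"
    }
  } else {
    new_ref <- diversify()
    state$n_chances <- config$max_chances
    state$event <- "diversify"
  }
  if (in_tabu(new_ref, state$tabu)) {   # random fallback must also be fresh
    repeat {
      new_ref <- random_mask(length(state$best_global))
      if (!in_tabu(new_ref, state$tabu)) break
    }
  }
  state$ref <- new_ref
  state$tabu <- c(state$tabu, list(new_ref))
  state
}

new_fs_run <- function(method, best_mask, best_fitness, history, config, objective) {
  structure(list(method = method, best_mask = best_mask,
                 best_fitness = best_fitness, history = history,
                 config = config, n_evals = objective$n_evals(),
                 objective_id = objective$id),
            class = "fs_run")
}

#' Run the bee-swarm feature-subset search
#'
#' Executes the full outer search: a random nonzero reference mask seeds the
#' first region; each iteration generates the region, runs every bee's local
#' search (mode per `config$local_search`, with the Q-modes sharing one
#' persistent learner state across bees and iterations), collects the dance
#' table, and advances the reference solution by [advance_reference()].
#' Stops at `max_iter` iterations or when `eval_budget` classifier
#' evaluations have been spent. The entire run is deterministic under
#' `config$seed`.
#'
#' @param objective a [mask_objective()] or [function_objective()].
#' @param config a [bso_config()].
#' @return An object of class `fs_run`: best mask and [fitness_result()],
#'   per-iteration history (`iteration`, `n_evaluations`, `best_fitness`,
#'   `n_selected`, `elapsed_s`), the config, and evaluation counts.
#' @export
run_bso <- function(objective, config = bso_config()) {
  stop_if_not(inherits(objective, "mask_objective"), "objective must be a mask_objective")
  n <- objective$n_features
  stop_if_not(config$flip <= n, "flip (%d) exceeds the feature count (%d)",
              config$flip, n)
  t0 <- proc.time()[["elapsed"]]
  local_seed(config$seed, {
    ref <- random_mask(n)
    ref_fit <- objective$evaluate(ref)
    state <- list(ref = ref, best_global = ref, best_global_fit = ref_fit,
                  tabu = list(ref), n_chances = config$max_chances)
    rlst <- if (config$local_search != "hill") rl_state(n, config$qlearn)
    hist <- vector("list", config$max_iter)
    for (iter in seq_len(config$max_iter)) {
      if (objective$n_evals() >= config$eval_budget) break
      state$candidates <- generate_search_region(state$ref, config)
      state$dance <- vector("list", config$nb)
      for (b in seq_len(config$nb)) {
        if (objective$n_evals() >= config$eval_budget) break
        res <- if (config$local_search == "hill") {
          hill_climb_local_search(state$candidates[[b]], objective, config$local_budget)
        } else {
          run_rl_local_search(state$candidates[[b]], state$best_global, objective,
                              budget = max(1L, config$local_budget),
                              state = rlst, reward = config$reward)
        }
        state$dance[[b]] <- list(mask = res$mask, fitness = res$fitness)
      }
      state$dance <- state$dance[!vapply(state$dance, is.null, logical(1))]
      if (length(state$dance) == 0L) break
      state <- advance_reference(state, config)
      hist[[iter]] <- data.frame(
        iteration = iter, n_evaluations = objective$n_evals(),
        best_fitness = state$best_global_fit$accuracy,
        n_selected = state$best_global_fit$n_selected,
        elapsed_s = proc.time()[["elapsed"]] - t0)
    }
    history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    method <- switch(config$local_search, "deep-q" = "baroque",
                     "tabular-q" = "qbso", hill = "bso")
    new_fs_run(method, state$best_global, state$best_global_fit, history,
               config, objective)
  })
}

#' Deep-Q-only feature-subset search
#'
#' The DQN component run standalone, without the bee-swarm outer loop: a
#' single learning trajectory from a random start, restricted toward the
#' best solution found so far (which replaces the swarm's best global
#' solution between chunks). Budget and reporting match [run_bso()] so the
#' two are comparable at a fixed evaluation budget.
#'
#' @inheritParams run_bso
#' @return An object of class `fs_run` (method `"dqn"`).
#' @export
run_dqn <- function(objective, config = bso_config()) {
  stop_if_not(inherits(objective, "mask_objective"), "objective must be a mask_objective")
  n <- objective$n_features
  t0 <- proc.time()[["elapsed"]]
  local_seed(config$seed, {
    qp <- config$qlearn; qp$mode <- "deep"
    rlst <- rl_state(n, qp)
    cur <- random_mask(n)
    best <- cur
    best_fit <- objective$evaluate(cur)
    chunk <- max(1L, config$local_budget)
    n_chunks <- config$max_iter * config$nb
    hist <- vector("list", n_chunks)
    for (i in seq_len(n_chunks)) {
      if (objective$n_evals() >= config$eval_budget) break
      res <- run_rl_local_search(cur, best, objective, budget = chunk,
                                 state = rlst, reward = config$reward)
      cur <- res$mask
      if (better(res$fitness, best_fit)) { best <- res$mask; best_fit <- res$fitness }
      hist[[i]] <- data.frame(
        iteration = i, n_evaluations = objective$n_evals(),
        best_fitness = best_fit$accuracy, n_selected = best_fit$n_selected,
        elapsed_s = proc.time()[["elapsed"]] - t0)
    }
    history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    new_fs_run("dqn", best, best_fit, history, config, objective)
  })
}
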