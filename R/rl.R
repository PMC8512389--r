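#' Encode a mask as a per-agent observation
#'
#' Each candidate feature is an agent; agent `u`'s observation of a solution
#' mask is a binary vector of length `2N`: first a one-hot block whose entry
#' `u` equals the mask's bit `u` (all-zero when the agent's feature is
#' unselected), then the full selection mask.
#'
#' @param mask 0/1 solution mask of length N.
#' @param agent agent index `u` in `1..N`.
#' @return Integer 0/1 vector of length `2N`.
#' @examples
#' encode_observation(c(1, 0, 1, 1, 0), 3)  # 0 0 1 0 0 1 0 1 1 0
#' @export
encode_observation <- function(mask, agent) {
  mask <- as_mask(mask)
  n <- length(mask)
  stop_if_not(is_count(agent, 1L) && agent <= n, "agent index out of range 1..%d", n)
  onehot <- integer(n)
  onehot[agent] <- mask[agent]
  c(onehot, mask)
}

#' Positions where a mask may be flipped
#'
#' The local-search neighborhood restriction: only bits where the current
#' mask differs from the best global solution (their exclusive-or) may be
#' flipped, so every accepted flip moves the trajectory toward the best
#' known solution. When the two masks coincide the restriction degenerates;
#' the fallback then allows every position, so agents are not frozen at the
#' start of a search.
#'
#' @param mask,best_global equal-length 0/1 masks.
#' @return Integer vector of 1-based flippable positions.
#' @examples
#' allowed_flips(c(1, 0, 1, 1, 0), c(0, 1, 1, 0, 1))  # 1 2 4 5
#' @export
allowed_flips <- function(mask, best_global) {
  mask <- as_mask(mask); best_global <- as_mask(best_global)
  stop_if_not(length(mask) == length(best_global), "masks must have equal length")
  pos <- which(mask != best_global)
  if (length(pos) == 0L) pos <- seq_along(mask)
  pos
}

#' Reward parameters
#'
#' @param penalty_coeff multiplier on a negative accuracy change (fixed at
#'   0.5 in the reference design).
#' @param delta design factor scaling the reward when accuracy is unchanged
#'   (> 0); its sign then encodes whether the feature count went down.
#' @return An object of class `reward_params`.
#' @export
reward_params <- function(penalty_coeff = 0.5, delta = 0.1) {
  stop_if_not(is.numeric(delta) && delta > 0, "delta must be > 0")
  structure(list(penalty_coeff = penalty_coeff, delta = delta),
            class = "reward_params")
}

#' Three-branch local-search reward
#'
#' The reward an agent receives after its step changes the evaluated
#' accuracy from `acc_prev` to `acc_curr` and the selected-feature count
#' from `k_prev` to `k_curr`:
#' accuracy up — reward is the new accuracy itself; accuracy down — reward
#' is `penalty_coeff * (acc_curr - acc_prev)`, a negative value; accuracy
#' unchanged — reward is `acc_curr * delta`, positive exactly when the
#' feature count decreased (`k_prev > k_curr`) and negative otherwise, so
#' equal-accuracy moves are steered toward smaller subsets.
#'
#' @param params a [reward_params()].
#' @param acc_prev,acc_curr accuracies in `[0, 1]`.
#' @param k_prev,k_curr selected-feature counts before and after.
#' @return Scalar reward.
#' @examples
#' p <- reward_params()
#' compute_reward(p, 0.80, 0.90, 10, 10)  #  0.90
#' compute_reward(p, 0.90, 0.80, 10, 10)  # -0.05
#' compute_reward(p, 0.90, 0.90, 10, 8)   #  0.09
#' @export
compute_reward <- function(params, acc_prev, acc_curr, k_prev, k_curr) {
  stop_if_not(inherits(params, "reward_params"), "params must be reward_params")
  stop_if_not(acc_prev >= 0 && acc_prev <= 1 && acc_curr >= 0 && acc_curr <= 1,
              "accuracies must lie in [0, 1]")
  if (acc_prev < acc_curr) return(acc_curr)
  if (acc_prev > acc_curr) return(params$penalty_coeff * (acc_curr - acc_prev))
  sgn <- if (k_prev > k_curr) 1 else -1
  sgn * acc_curr * params$delta
}

#' One-step Q-value update
#'
#' The temporal-difference update
#' `q_new = q + alpha * (r + gamma * max_next_q - q)`; terminal transitions
#' pass `max_next_q = 0`.
#'
#' @param q_current current Q-value.
#' @param r observed reward.
#' @param max_next_q maximum Q-value of the successor state.
#' @param alpha learning rate in (0, 1].
#' @param gamma discount factor in \[0, 1).
#' @return Updated Q-value.
#' @export
q_update <- function(q_current, r, max_next_q, alpha, gamma) {
  stop_if_not(alpha > 0 && alpha <= 1, "alpha must lie in (0, 1]")
  stop_if_not(gamma >= 0 && gamma < 1, "gamma must lie in [0, 1)")
  q_current + alpha * (r + gamma * max_next_q - q_current)
}

#' Experience replay buffer
#'
#' Fixed-capacity first-in-first-out store of `(s, a, r, s', terminal)`
#' transitions, sampled uniformly without replacement to decorrelate
#' training batches.
#'
#' @param capacity maximum number of stored experiences.
#' @return An object of class `replay_buffer` with functions `add(exp)`,
#'   `size()` and the sampler is [replay_sample()].
#' @export
replay_buffer <- function(capacity = 10000L) {
  stop_if_not(is_count(capacity, 1L), "capacity must be >= 1")
  env <- new.env(parent = emptyenv())
  env$items <- vector("list", capacity)
  env$n <- 0L       # filled slots
  env$head <- 0L    # next write position (circular)
  add <- function(exp) {
    env$head <- (env$head %% capacity) + 1L
    env$items[[env$head]] <- exp
    env$n <- min(env$n + 1L, capacity)
    invisible(NULL)
  }
  structure(list(add = add, size = function() env$n,
                 get = function(i) env$items[[i]], capacity = capacity),
            class = "replay_buffer")
}

#' Sample a training mini-batch from a replay buffer
#'
#' @param buffer a [replay_buffer()].
#' @param batch_size number of experiences to draw (uniform, without
#'   replacement). An underfull buffer is an error; callers wait until the
#'   warm-up fill is reached.
#' @return List of experiences.
#' @export
replay_sample <- function(buffer, batch_size) {
  stop_if_not(inherits(buffer, "replay_buffer"), "buffer must be a replay_buffer")
  n <- buffer$size()
  stop_if_not(batch_size <= n, "buffer holds %d experiences; cannot sample %d", n, batch_size)
  ix <- sample.int(n, batch_size)
  lapply(ix, buffer$get)
}

# single-hidden-layer value network: 2N -> hid (ReLU) -> 2 (linear)
qnet_init <- function(n_in, hid) {
  list(params = list(W1 = he_init(n_in, hid), b1 = numeric(hid),
                     W2 = he_init(hid, 2L), b2 = numeric(2L)),
       opt = NULL, n_in = n_in)
}

qnet_forward <- function(net, X) {
  H <- pmax(X %*% net$params$W1 + matrix(net$params$b1, nrow(X), length(net$params$b1),
                                         byrow = TRUE), 0)
  Q <- H %*% net$params$W2 + matrix(net$params$b2, nrow(X), 2L, byrow = TRUE)
  list(Q = Q, H = H)
}

batch_matrices <- function(batch) {
  list(s = do.call(rbind, lapply(batch, `[[`, "s")),
       a = vapply(batch, `[[`, numeric(1), "a"),
       r = vapply(batch, `[[`, numeric(1), "r"),
       s2 = do.call(rbind, lapply(batch, `[[`, "s2")),
       term = vapply(batch, `[[`, logical(1), "terminal"))
}

#' One deep-Q training step
#'
#' Computes targets `r + gamma * max_a' Q_target(s', a')` (just `r` on
#' terminal transitions), takes one Adam step on the squared error between
#' the network's value for each taken action and its target, and leaves the
#' target network untouched — callers copy it at the copy period.
#'
#' @param net the trained value network (from the internal constructor used
#'   by [rl_state()]).
#' @param target_net the periodically copied target network.
#' @param batch list of experiences as sampled by [replay_sample()].
#' @param gamma discount factor.
#' @param lr Adam learning rate.
#' @return List with the updated `net` and the scalar `loss` before the step.
#' @export
dqn_train_step <- function(net, target_net, batch, gamma, lr = 1e-3) {
  stop_if_not(length(batch) >= 1, "batch must be non-empty")
  bm <- batch_matrices(batch)
  B <- nrow(bm$s)
  q_next <- qnet_forward(target_net, bm$s2)$Q
  target <- bm$r + gamma * apply(q_next, 1, max) * !bm$term
  fw <- qnet_forward(net, bm$s)
  a_ix <- cbind(seq_len(B), bm$a + 1L)
  pred <- fw$Q[a_ix]
  loss <- mean((pred - target)^2)
  dQ <- matrix(0, B, 2L)
  dQ[a_ix] <- 2 * (pred - target) / B
  g <- list(W2 = crossprod(fw$H, dQ), b2 = colSums(dQ))
  dH <- dQ %*% t(net$params$W2) * (fw$H > 0)
  g$W1 <- crossprod(bm$s, dH); g$b1 <- colSums(dH)
  if (is.null(net$opt)) net$opt <- adam_init(net$params)
  upd <- adam_step(net$params, g, net$opt, lr)
  net$params <- upd$params; net$opt <- upd$opt
  list(net = net, loss = loss)
}

#' Q-learning parameters
#'
#' Hyperparameters for the local-search learner. `mode = "tabular"` keys a
#' lookup table by (observation, action) — the QBSO-style comparison mode —
#' while `mode = "deep"` trains the shared value network with experience
#' replay and a target network.
#'
#' @param alpha tabular learning rate in (0, 1].
#' @param gamma discount factor in \[0, 1).
#' @param epsilon0,epsilon_min,epsilon_decay exploration schedule: the
#'   exploration rate starts at `epsilon0` and is multiplied by
#'   `epsilon_decay` each step, floored at `epsilon_min`.
#' @param mode `"deep"` or `"tabular"`.
#' @param hid_num hidden-layer width of the value network.
#' @param lr network learning rate (Adam).
#' @param buffer_capacity,batch_size,target_copy,warmup,train_every replay
#'   and target-network schedule: train every `train_every` steps once
#'   `warmup` experiences are stored, copying the target every
#'   `target_copy` training steps.
#' @return An object of class `qlearn_params`.
#' @export
qlearn_params <- function(alpha = 0.1, gamma = 0.9, epsilon0 = 1.0,
                          epsilon_min = 0.05, epsilon_decay = 0.995,
                          mode = c("deep", "tabular"), hid_num = 64L, lr = 1e-3,
                          buffer_capacity = 10000L, batch_size = 32L,
                          target_copy = 100L, warmup = 200L, train_every = 1L) {
  mode <- match.arg(mode)
  stop_if_not(alpha > 0 && alpha <= 1, "alpha must lie in (0, 1]")
  stop_if_not(gamma >= 0 && gamma < 1, "gamma must lie in [0, 1)")
  structure(list(alpha = alpha, gamma = gamma, epsilon0 = epsilon0,
                 epsilon_min = epsilon_min, epsilon_decay = epsilon_decay,
                 mode = mode, hid_num = as.integer(hid_num), lr = lr,
                 buffer_capacity = as.integer(buffer_capacity),
                 batch_size = as.integer(batch_size),
                 target_copy = as.integer(target_copy),
                 warmup = as.integer(warmup),
                 train_every = as.integer(train_every)),
            class = "qlearn_params")
}

#' Persistent learner state for the RL local search
#'
#' Holds everything the local search learns — the Q-table (tabular mode) or
#' the value network, its target copy and the replay buffer (deep mode) —
#' plus the exploration rate. The state persists across bees and outer
#' iterations, so every bee learns from the swarm's accumulated experience.
#'
#' @param n_features mask length N (observations have length 2N).
#' @param qlearn a [qlearn_params()].
#' @return An environment of class `rl_state`.
#' @export
rl_state <- function(n_features, qlearn = qlearn_params()) {
  st <- new.env(parent = emptyenv())
  st$qlearn <- qlearn
  st$eps <- qlearn$epsilon0
  st$n_features <- as.integer(n_features)
  if (qlearn$mode == "tabular") {
    st$qtable <- new.env(parent = emptyenv())
  } else {
    st$net <- qnet_init(2L * n_features, qlearn$hid_num)
    st$target <- st$net
    st$buffer <- replay_buffer(qlearn$buffer_capacity)
    st$train_count <- 0L
  }
  st$step_count <- 0L
  st$cursor <- 0L   # round-robin agent cursor, persisted across searches so
                    # every agent acts even when one search's budget < N
  class(st) <- "rl_state"
  st
}

q_table_get <- function(qtable, key) {
  v <- qtable[[key]]
  if (is.null(v)) 0 else v
}

# Q-values for both actions of observation s (tabular or network)
state_action_values <- function(st, s) {
  if (st$qlearn$mode == "tabular") {
    k <- paste(s, collapse = "")
    c(q_table_get(st$qtable, paste0(k, "|0")), q_table_get(st$qtable, paste0(k, "|1")))
  } else {
    as.numeric(qnet_forward(st$net, matrix(s, 1L))$Q)
  }
}

#' Serialize a tabular Q-table
#'
#' @param st an [rl_state()] in tabular mode.
#' @return data.frame of (observation, action, q), sorted by key, for
#'   inspection or text export.
#' @export
q_table_export <- function(st) {
  stop_if_not(inherits(st, "rl_state") && st$qlearn$mode == "tabular",
              "st must be a tabular-mode rl_state")
  keys <- sort(ls(st$qtable))
  if (length(keys) == 0)
    return(data.frame(observation = character(0), action = integer(0), q = numeric(0)))
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(observation = vapply(parts, `[[`, character(1), 1L),
             action = as.integer(vapply(parts, `[[`, character(1), 2L)),
             q = vapply(keys, function(k) st$qtable[[k]], numeric(1)),
             row.names = NULL)
}

#' Multi-agent Q-learning local search over feature masks
#'
#' One bee's local search. Agents (one per feature) step round-robin in
#' index order; at each step the owning agent observes the current mask
#' ([encode_observation()]), picks epsilon-greedily between keeping and
#' flipping its bit — flips are restricted to the positions where the mask
#' differs from `best_global` ([allowed_flips()]), and a flip that would
#' empty the mask is not available — the new mask is evaluated (memoized),
#' the three-branch reward is computed, the transition is stored, and the
#' learner is updated (tabular Q-update, or a replay-buffer training step
#' per the schedule). Returns the best mask visited by the tie-break-aware
#' comparison [better()], which is never worse than the start.
#'
#' @param start 0/1 starting mask (at least one bit set).
#' @param best_global 0/1 mask the neighborhood is restricted toward.
#' @param objective a [mask_objective()] or [function_objective()].
#' @param budget number of agent steps (>= 1).
#' @param state an [rl_state()]; pass the same state across calls to let
#'   learning persist. Defaults to a fresh deep-mode state.
#' @param reward a [reward_params()].
#' @return List with `mask`, `fitness` ([fitness_result()]), the (updated)
#'   `state`, and `trace` (data.frame of per-step accuracy and Hamming
#'   distance to `best_global`).
#' @export
run_rl_local_search <- function(start, best_global, objective, budget,
                                state = NULL, reward = reward_params()) {
  stop_if_not(is_count(budget, 1L), "budget must be >= 1")
  stop_if_not(inherits(objective, "mask_objective"), "objective must be a mask_objective")
  cur <- as_mask(start)
  best_global <- as_mask(best_global)
  n <- length(cur)
  stop_if_not(n == objective$n_features, "mask length must match the objective")
  if (is.null(state)) state <- rl_state(n)
  qp <- state$qlearn
  fit_cur <- objective$evaluate(cur)
  best <- cur; fit_best <- fit_cur
  acc_tr <- ham_tr <- numeric(budget)
  for (step in seq_len(budget)) {
    u <- (state$cursor %% n) + 1L
    state$cursor <- state$cursor + 1L
    allowed <- allowed_flips(cur, best_global)
    can_flip <- (u %in% allowed) && !(sum(cur) == 1L && cur[u] == 1L)
    a <- 0L
    if (can_flip) {
      if (stats::runif(1) < state$eps) {
        a <- sample(c(0L, 1L), 1L)
      } else {
        q <- state_action_values(state, encode_observation(cur, u))
        a <- which.max(q) - 1L
      }
    }
    new <- cur
    if (a == 1L) new[u] <- 1L - new[u]
    fit_new <- objective$evaluate(new)
    r <- compute_reward(reward, fit_cur$accuracy, fit_new$accuracy,
                        fit_cur$n_selected, fit_new$n_selected)
    s <- encode_observation(cur, u)
    s2 <- encode_observation(new, u)
    terminal <- step == budget
    if (qp$mode == "tabular") {
      k <- paste0(paste(s, collapse = ""), "|", a)
      max_next <- if (terminal) 0 else max(state_action_values(state, s2))
      state$qtable[[k]] <- q_update(q_table_get(state$qtable, k), r, max_next,
                                    qp$alpha, qp$gamma)
    } else {
      state$buffer$add(list(s = s, a = a, r = r, s2 = s2, terminal = terminal))
      if (state$buffer$size() >= qp$warmup && state$step_count %% qp$train_every == 0L) {
        batch <- replay_sample(state$buffer, min(qp$batch_size, state$buffer$size()))
        upd <- dqn_train_step(state$net, state$target, batch, qp$gamma, qp$lr)
        state$net <- upd$net
        state$train_count <- state$train_count + 1L
        if (state$train_count %% qp$target_copy == 0L) state$target <- state$net
      }
    }
    cur <- new; fit_cur <- fit_new
    if (better(fit_new, fit_best)) { best <- new; fit_best <- fit_new }
    acc_tr[step] <- fit_cur$accuracy
    ham_tr[step] <- hamming(cur, best_global)
    state$eps <- max(qp$epsilon_min, state$eps * qp$epsilon_decay)
    state$step_count <- state$step_count + 1L
  }
  list(mask = best, fitness = fit_best, state = state,
       trace = data.frame(step = seq_len(budget), accuracy = acc_tr,
                          hamming_to_best = ham_tr))
}
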