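test_that("observation encoding puts the one-hot block before the mask", {
  expect_equal(encode_observation(c(1, 0, 1, 1, 0), 3),
               c(0, 0, 1, 0, 0, 1, 0, 1, 1, 0))
  # an unselected agent's one-hot block is all zero
  expect_equal(encode_observation(c(1, 0, 1, 1, 0), 2),
               c(0, 0, 0, 0, 0, 1, 0, 1, 1, 0))
  for (u in 1:5) expect_length(encode_observation(c(1, 0, 1, 1, 0), u), 10)
  expect_error(encode_observation(c(1, 0, 1), 4), "out of range")
})

test_that("allowed flips are the XOR positions with a full-set fallback", {
  expect_equal(allowed_flips(c(1, 0, 1, 1, 0), c(0, 1, 1, 0, 1)), c(1, 2, 4, 5))
  expect_equal(allowed_flips(c(1, 0, 1), c(1, 0, 1)), 1:3)   # degenerate fallback
  expect_equal(allowed_flips(c(1, 1, 0), c(0, 0, 1)), 1:3)   # complementary
  expect_error(allowed_flips(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("the reward follows the three-branch rule with signed ties", {
  p <- reward_params()
  expect_equal(compute_reward(p, 0.80, 0.90, 10, 10), 0.90)
  expect_equal(compute_reward(p, 0.90, 0.80, 10, 10), -0.05)
  expect_equal(compute_reward(p, 0.90, 0.90, 10, 8), 0.09)
  expect_equal(compute_reward(p, 0.90, 0.90, 8, 10), -0.09)
  expect_equal(compute_reward(p, 0.90, 0.90, 8, 8), -0.09)  # no shrink, negative
  # sign contract over random cases
  set.seed(3)
  for (i in 1:50) {
    a1 <- runif(1); a2 <- runif(1)
    k1 <- sample(1:20, 1); k2 <- sample(1:20, 1)
    r <- compute_reward(p, a1, a2, k1, k2)
    if (a2 > a1) expect_gt(r, 0)
    if (a2 < a1) expect_lt(r, 0)
    if (a2 == a1) expect_equal(sign(r), ifelse(k1 > k2, 1, -1))
  }
})

test_that("the Q update matches the temporal-difference arithmetic", {
  expect_equal(q_update(2, 1, 0.5, 1e-9, 0.9), 2, tolerance = 1e-6)
  expect_equal(q_update(2, 1, 0.5, 1, 0), 1)       # myopic limit
  expect_equal(q_update(0, 1, 2, 0.5, 0.9), 1.4)
  expect_error(q_update(0, 1, 2, 0, 0.9), "alpha")
})

test_that("replay sampling is uniform, seeded, and guards underfull buffers", {
  buf <- replay_buffer(10)
  for (i in 1:10) buf$add(list(s = i, a = 0L, r = 0, s2 = i, terminal = FALSE))
  expect_equal(buf$size(), 10L)
  expect_error(replay_sample(buf, 11), "cannot sample")
  # batch = buffer size is a permutation
  set.seed(1)
  full <- replay_sample(buf, 10)
  expect_setequal(vapply(full, `[[`, numeric(1), "s"), 1:10)
  # determinism under a fixed seed
  b1 <- local({ set.seed(9); replay_sample(buf, 3) })
  b2 <- local({ set.seed(9); replay_sample(buf, 3) })
  expect_identical(b1, b2)
  # frequencies within 3 binomial SDs of uniform over many draws
  set.seed(2)
  counts <- integer(10)
  n_draws <- 4000
  for (i in seq_len(n_draws)) {
    ix <- vapply(replay_sample(buf, 3), `[[`, numeric(1), "s")
    counts[ix] <- counts[ix] + 1L
  }
  p <- 3 / 10
  sd3 <- 3 * sqrt(n_draws * p * (1 - p))
  expect_true(all(abs(counts - n_draws * p) < sd3))
  # FIFO eviction beyond capacity
  buf$add(list(s = 11, a = 0L, r = 0, s2 = 11, terminal = FALSE))
  expect_equal(buf$size(), 10L)
})

test_that("deep-Q training fits fixed targets and target copies are exact", {
  set.seed(5)
  st <- rl_state(4, qlearn_params(hid_num = 16))
  batch <- lapply(1:8, function(i) {
    list(s = as.integer(intToBits(i)[1:8]), a = i %% 2L, r = runif(1),
         s2 = as.integer(intToBits(i + 1)[1:8]), terminal = TRUE)
  })
  # all-terminal batch: targets are exactly the rewards; repeated fitting of
  # the same batch is a convergent regression
  first <- dqn_train_step(st$net, st$target, batch, gamma = 0.9, lr = 1e-2)
  net <- first$net
  loss <- first$loss
  for (i in 1:50) {
    stp <- dqn_train_step(net, st$target, batch, gamma = 0.9, lr = 1e-2)
    net <- stp$net; loss <- stp$loss
  }
  expect_lt(loss, first$loss / 10)
  # after a copy event the two networks agree everywhere
  target <- net
  x <- matrix(rnorm(3 * 8), 3, 8)
  expect_equal(baroque:::qnet_forward(net, x)$Q,
               baroque:::qnet_forward(target, x)$Q)
})

test_that("restricted trajectories never move away from the best global mask", {
  target <- toy_target(10)
  fn <- toy_fitness(target)
  for (s in 1:5) {
    obj <- function_objective(fn, 10)
    res <- local({
      set.seed(s)
      start <- random_mask(10)
      run_rl_local_search(start, target, obj, budget = 40,
                          state = rl_state(10, qlearn_params(mode = "tabular")))
    })
    # while the restriction is active (distance still positive) every step
    # keeps or reduces the Hamming distance; once it hits zero the
    # unrestricted fallback applies and the invariant no longer binds
    d <- res$trace$hamming_to_best
    upto <- if (any(d == 0)) which(d == 0)[1] else length(d)
    if (upto > 1) expect_true(all(diff(d[seq_len(upto)]) <= 0))
  }
})

test_that("budget-1 search returns the better of start and one neighbor", {
  fn <- toy_fitness(toy_target(6))
  obj <- function_objective(fn, 6)
  set.seed(2)
  start <- random_mask(6)
  res <- run_rl_local_search(start, start, obj, budget = 1,
                             state = rl_state(6, qlearn_params(mode = "tabular",
                                                               epsilon0 = 1)))
  expect_lte(hamming(res$mask, start), 1)
  expect_gte(res$fitness$accuracy, fn(start))
  # never worse than the start by `better`
  expect_false(better(fitness_result(fn(start), max(1, sum(start))), res$fitness))
})

test_that("the learner reaches the enumerated optimum on a toy landscape", {
  target <- toy_target(8)
  fn <- toy_fitness(target)
  opt <- enumerate_optimum(fn, 8)
  for (mode in c("tabular", "deep")) {
    hits <- 0L
    for (s in 1:5) {
      obj <- function_objective(fn, 8)
      res <- local({
        set.seed(s)
        st <- rl_state(8, qlearn_params(mode = mode, warmup = 50))
        best <- random_mask(8)
        out <- NULL
        for (chunk in 1:10) {              # refresh the restriction periodically
          out <- run_rl_local_search(if (is.null(out)) best else out$mask,
                                     best, obj, budget = 50, state = st)
          if (better(out$fitness, fitness_result(fn(best), max(1, sum(best)))))
            best <- out$mask
        }
        out
      })
      if (res$fitness$accuracy == opt$value) hits <- hits + 1L
    }
    expect_gte(hits, 4L)
  }
})

test_that("tabular Q-values converge under repeated identical transitions", {
  st <- rl_state(4, qlearn_params(mode = "tabular", alpha = 0.5, gamma = 0))
  fn <- function(mask) sum(mask) / 4
  obj <- function_objective(fn, 4)
  set.seed(1)
  for (i in 1:30) {
    run_rl_local_search(c(1L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L), obj, budget = 8,
                        state = st)
  }
  q1 <- q_table_export(st)
  run_rl_local_search(c(1L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L), obj, budget = 8,
                      state = st)
  q2 <- q_table_export(st)
  shared <- intersect(paste(q1$observation, q1$action),
                      paste(q2$observation, q2$action))
  m1 <- q1$q[match(shared, paste(q1$observation, q1$action))]
  m2 <- q2$q[match(shared, paste(q2$observation, q2$action))]
  expect_equal(m1, m2, tolerance = 0.05)
})
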