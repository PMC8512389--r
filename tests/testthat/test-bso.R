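test_that("search-region strategies flip the documented positions", {
  cfg <- bso_config(nb = 10, flip = 4)
  ref <- rep(0L, 16)
  region <- local({ set.seed(1); generate_search_region(ref, cfg) })
  flips0 <- lapply(region, function(m) which(m != ref) - 1L)
  expect_equal(flips0[[1]], c(0L, 4L, 8L, 12L))
  expect_equal(flips0[[2]], c(1L, 5L, 9L, 13L))
  expect_equal(flips0[[3]], c(2L, 6L, 10L, 14L))
  expect_equal(flips0[[4]], c(3L, 7L, 11L, 15L))
  expect_equal(flips0[[5]], 0:3)
  expect_equal(flips0[[6]], 4:7)
  expect_equal(flips0[[7]], 8:11)
  expect_equal(flips0[[8]], 12:15)
  # strategy 3 remainder flips ceiling(N/flip) random positions
  expect_length(flips0[[9]], 4)
  expect_length(flips0[[10]], 4)
})

test_that("regions keep their distance guarantees on a nonzero reference", {
  set.seed(3)
  ref <- random_mask(16)
  cfg <- bso_config(nb = 10, flip = 4)
  region <- generate_search_region(ref, cfg)
  expect_length(region, 10)
  for (m in region) expect_gte(hamming(m, ref), 1)
  # first-strategy mask i sits at distance ceiling((N - i) / flip)
  for (i in 0:3) expect_equal(hamming(region[[i + 1]], ref), ceiling((16 - i) / 4))
  # no duplicates among candidates
  keys <- vapply(region, mask_key, character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_error(generate_search_region(ref, bso_config(flip = 17)), "flip")
})

test_that("all-zero candidates are repaired", {
  ref <- rep(1L, 8)
  cfg <- bso_config(nb = 4, flip = 1)   # strategy 1 flips every bit -> all zero
  region <- local({ set.seed(2); generate_search_region(ref, cfg) })
  for (m in region) expect_gte(sum(m), 1)
})

test_that("hill climbing reaches the optimum of a unimodal landscape", {
  target <- toy_target(8)
  fn <- toy_fitness(target)
  # oracle: enumeration shows the landscape's only optimum is the target
  opt <- enumerate_optimum(fn, 8)
  expect_equal(opt$mask, target)
  set.seed(4)
  for (i in 1:5) {
    obj <- function_objective(fn, 8)
    res <- hill_climb_local_search(random_mask(8), obj, budget = 200)
    expect_equal(res$mask, target)
    expect_equal(res$fitness$accuracy, opt$value)
    # monotone accepted-move trace
    expect_true(all(diff(res$trace) > 0) || length(res$trace) == 1)
  }
  # zero budget returns the evaluated start
  obj <- function_objective(fn, 8)
  start <- random_mask(8)
  res0 <- hill_climb_local_search(start, obj, budget = 0)
  expect_equal(res0$mask, start)
})

test_that("reference advancement follows the chance counter", {
  cfg <- bso_config(nb = 3, flip = 2, max_chances = 3)
  n <- 6
  mk <- function(...) as.integer(c(...))
  good <- fitness_result(0.9, 3)
  base <- list(best_global = mk(1, 1, 0, 0, 0, 0), best_global_fit = good,
               tabu = list(mk(1, 1, 0, 0, 0, 0)), n_chances = 3L)
  cands <- list(mk(0, 0, 0, 1, 1, 1), mk(1, 0, 1, 0, 1, 0))
  # improvement branch: chances reset, best_global updated
  st <- base
  st$dance <- list(list(mask = mk(1, 0, 1, 1, 0, 0), fitness = fitness_result(0.95, 3)))
  st$candidates <- cands
  st <- advance_reference(st, cfg)
  expect_equal(st$event, "improve")
  expect_equal(st$best_global_fit$accuracy, 0.95)
  expect_equal(st$n_chances, 3L)
  # with max_chances = 3, diversification fires on the third consecutive
  # non-improving iteration (hand-traced chance counter: 3 -> 2 -> 1 -> 0)
  st <- base; st$candidates <- cands
  events <- character(0)
  for (i in 1:3) {
    unit <- integer(n); unit[i] <- 1L     # fresh dance mask each iteration
    st$dance <- list(list(mask = unit, fitness = fitness_result(0.5, 1)))
    st$candidates <- cands
    st <- local({ set.seed(i); advance_reference(st, cfg) })
    events <- c(events, st$event)
  }
  expect_equal(events, c("intensify", "intensify", "diversify"))
  # the diversified reference is never a tabu member
  keys <- vapply(st$tabu[-length(st$tabu)], mask_key, character(1))
  expect_false(mask_key(st$ref) %in% keys)
})

test_that("run_bso finds the enumerated optimum on toy landscapes", {
  target <- toy_target(8)
  fn <- toy_fitness(target)
  opt <- enumerate_optimum(fn, 8)
  for (mode in c("hill", "tabular-q", "deep-q")) {
    hits <- 0L
    for (s in 1:5) {
      obj <- function_objective(fn, 8)
      cfg <- bso_config(nb = 6, flip = 3, max_iter = 20, local_search = mode,
                        local_budget = 24, seed = s,
                        qlearn = qlearn_params(warmup = 50))
      run <- run_bso(obj, cfg)
      if (run$best_fitness$accuracy == opt$value) hits <- hits + 1L
      # invariant: best-so-far trace is non-decreasing
      expect_true(all(diff(run$history$best_fitness) >= 0))
    }
    expect_gte(hits, 4L)
  }
})

test_that("runs are deterministic under a fixed seed and tabu never repeats", {
  target <- toy_target(10)
  fn <- toy_fitness(target)
  cfg <- bso_config(nb = 5, flip = 3, max_iter = 10, local_search = "hill",
                    local_budget = 15, seed = 11)
  r1 <- run_bso(function_objective(fn, 10), cfg)
  r2 <- run_bso(function_objective(fn, 10), cfg)
  expect_identical(r1$best_mask, r2$best_mask)
  expect_identical(r1$history[setdiff(names(r1$history), "elapsed_s")],
                   r2$history[setdiff(names(r2$history), "elapsed_s")])
})
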