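test_that("genome decoding applies the 0.5 threshold and repairs empties", {
  expect_equal(decode_genome(c(0.49, 0.51)), c(0L, 1L))
  expect_equal(decode_genome(c(0.5, 0.2)), c(1L, 0L))     # boundary selects
  expect_equal(decode_genome(c(0.1, 0.4)), c(0L, 1L))     # empty -> largest gene
})

test_that("GA with elitism keeps a non-decreasing best trace", {
  fn <- toy_fitness(toy_target(8))
  obj <- function_objective(fn, 8)
  run <- run_ga(obj, ga_config(pop_size = 10, generations = 15,
                               crossover_rate = 0, mutation_rate = 0, seed = 2))
  expect_true(all(diff(run$history$best_fitness) >= 0))
})

test_that("BPSO resolves the sigmoid boundary as select and improves monotonically", {
  # zero velocity -> sigmoid 0.5 -> selected at threshold 0.5
  obj <- function_objective(function(m) sum(m) / 4, 4)
  run <- run_bpso(obj, bpso_config(swarm_size = 4, iterations = 5, seed = 1))
  expect_true(all(diff(run$history$best_fitness) >= 0))
  expect_s3_class(run$best_fitness, "fitness_result")
  expect_gte(sum(run$best_mask), 1)
})

test_that("ACO pheromones start symmetric and reinforce persistent features", {
  # equal pheromones: inclusion probability exactly one half
  expect_equal(baroque:::aco_inclusion_prob(rep(1, 8)), rep(0.5, 8))
  expect_equal(baroque:::aco_inclusion_prob(rep(7, 3)), rep(0.5, 3))
  # closed-form recursion oracle: a feature deposited every iteration ends at
  # tau0 * rho^T + deposit * sum(rho^(T-i)); never-selected ends at tau0 * rho^T
  fn <- function(m) if (m[1] == 1L) 0.9 else 0.1   # feature 1 always in best ant
  obj <- function_objective(fn, 6)
  cfg <- aco_config(n_ants = 10, iterations = 10, seed = 3)
  run <- run_aco(obj, cfg)
  expect_equal(run$best_mask[1], 1L)
  rho <- cfg$retention; T <- 10
  upper_never <- cfg$tau0 * rho^T                     # never-deposited value
  deposited_always <- cfg$tau0 * rho^T +
    cfg$deposit * sum(rho^(T - seq_len(T)))
  expect_equal(run$pheromone[1], deposited_always, tolerance = 1e-10)
  expect_gt(run$pheromone[1], max(run$pheromone[-1]) - 1e-12)
  expect_true(any(abs(run$pheromone[-1] - upper_never) < 1e-10) ||
                all(run$pheromone[-1] > upper_never))
})

test_that("all three comparators find the enumerated optimum on toy landscapes", {
  target <- toy_target(8)
  fn <- toy_fitness(target)
  opt <- enumerate_optimum(fn, 8)
  runners <- list(
    ga = function(obj, s) run_ga(obj, ga_config(pop_size = 16, generations = 30, seed = s)),
    bpso = function(obj, s) run_bpso(obj, bpso_config(swarm_size = 16, iterations = 30, seed = s)),
    aco = function(obj, s) run_aco(obj, aco_config(iterations = 40, seed = s)))
  for (nm in names(runners)) {
    hits <- 0L
    for (s in 1:5) {
      run <- runners[[nm]](function_objective(fn, 8), s)
      if (run$best_fitness$accuracy == opt$value) hits <- hits + 1L
    }
    expect_gte(hits, 4L)
  }
})

test_that("comparator runs are deterministic and share the report schema", {
  fn <- toy_fitness(toy_target(8))
  for (runner in list(function(o, s) run_ga(o, ga_config(generations = 5, seed = s)),
                      function(o, s) run_bpso(o, bpso_config(iterations = 5, seed = s)),
                      function(o, s) run_aco(o, aco_config(iterations = 5, seed = s)))) {
    r1 <- runner(function_objective(fn, 8), 7)
    r2 <- runner(function_objective(fn, 8), 7)
    expect_identical(r1$best_mask, r2$best_mask)
    expect_s3_class(r1, "fs_run")
    expect_true(all(c("iteration", "n_evaluations", "best_fitness", "n_selected")
                    %in% names(r1$history)))
  }
})
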