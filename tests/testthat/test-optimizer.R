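sphere <- function(x) sum(x^2)

test_that("initialization respects bounds, evaluates agents and is seeded", {
  cfg <- optimizer_config(bounds = c(-1, 1), seed = 1L)
  set.seed(cfg$seed)
  pop <- init_population(cfg, dim = 3L, sphere)
  expect_equal(dim(pop$position), c(10L, 3L))
  expect_true(all(pop$position >= -1 & pop$position <= 1))
  expect_true(all(pop$velocity == 0))
  # global best equals the minimum over directly re-evaluated agents
  direct <- apply(pop$position, 1L, sphere)
  expect_equal(pop$gbest_fitness, min(direct))
  expect_equal(pop$fitness, direct)
  # identical seed, identical population
  set.seed(cfg$seed)
  pop2 <- init_population(cfg, dim = 3L, sphere)
  expect_identical(pop, pop2)
})

test_that("configuration errors are rejected", {
  expect_error(optimizer_config(n_agents = 1L), "n_agents")
  expect_error(optimizer_config(inertia_min = 1, inertia_max = 0.5), "inertia")
  expect_error(optimizer_config(exploration_fraction = 0), "exploration")
  cfg <- optimizer_config(bounds = c(-Inf, Inf))
  expect_error(init_population(cfg, 2L, sphere), "finite")
})

test_that("PSO update follows the velocity rule and the inertia schedule", {
  # hand-evaluated rule: w = 0, c1 = 0, c2 = 1, r2 = 1, x = 2, gbest = 0
  cfg <- optimizer_config(n_agents = 2L, inertia_max = 0, inertia_min = 0,
                          c1 = 0, c2 = 1, bounds = c(-10, 10))
  pop <- manual_population(matrix(c(2, 0), 2, 1), matrix(0, 2, 1), sphere, cfg)
  pop <- pso_update(pop, cfg, sphere,
                    r1 = matrix(1, 2, 1), r2 = matrix(1, 2, 1))
  expect_equal(pop$position[1L, 1L], 0)

  # inertia schedule endpoints: velocity scales by 0.9 at t = 0, 0.6 at t = T
  cfg2 <- optimizer_config(n_agents = 2L, c1 = 0, c2 = 0, bounds = c(-10, 10),
                           n_iterations = 80L)
  base <- manual_population(matrix(0, 2, 1), matrix(1, 2, 1), sphere, cfg2)
  p0 <- pso_update(base, cfg2, sphere)
  expect_equal(p0$velocity[1L, 1L], 0.9)
  base$iteration <- 80L
  pT <- pso_update(base, cfg2, sphere)
  expect_equal(pT$velocity[1L, 1L], 0.6)

  # an agent with zero velocity sitting at both its pbest and gbest stays put
  cfg3 <- optimizer_config(n_agents = 2L, bounds = c(-10, 10))
  still <- manual_population(matrix(c(0, 0), 2, 1), matrix(0, 2, 1), sphere, cfg3)
  moved <- pso_update(still, cfg3, sphere)
  expect_equal(moved$position, still$position)
})

test_that("DTO update follows the flying and swimming rules", {
  # flying: zero velocity, K3 = K4 = 0, K5 = 1, r2 = 1, x = 3, gbest = 1
  cfg <- optimizer_config(n_agents = 2L, exploration_fraction = 0.5,
                          bounds = c(-10, 10))
  pop <- manual_population(matrix(c(1, 3), 2, 1), matrix(0, 2, 1), sphere, cfg)
  # agent 1 (fitness 1) is best and swims; agent 2 (fitness 9) flies
  out <- dto_update(pop, cfg, sphere,
                    K = list(K1 = 0, K2 = 1, K3 = 0, K4 = 0, K5 = 1),
                    r1 = matrix(1, 2, 1), r2 = matrix(1, 2, 1))
  expect_equal(out$position[2L, 1L], 1)  # flew to the global best
  # swimming with K1 = 0: x_best - 0 * |...| = x_best; agent 1 was x_best
  expect_equal(out$position[1L, 1L], 1)

  # elitism: global best never worsens across random DTO steps
  set.seed(5)
  pop <- init_population(cfg, 3L, sphere)
  prev <- pop$gbest_fitness
  for (i in 1:20) {
    pop <- dto_update(pop, cfg, sphere)
    expect_lte(pop$gbest_fitness, prev)
    prev <- pop$gbest_fitness
  }
})

test_that("strategy controller starts with DTO and swaps on stagnation", {
  cfg <- optimizer_config(swap_patience = 3L)
  st <- strategy_state()
  st <- choose_strategy(st, numeric(0), cfg)
  expect_equal(st$current_strategy, "DTO")
  # improvement keeps the strategy and resets the counter
  st$stagnation_count <- 2L
  st <- choose_strategy(st, c(1, 0.5), cfg)
  expect_equal(st$current_strategy, "DTO")
  expect_equal(st$stagnation_count, 0L)
  # a flat history for swap_patience iterations forces the swap and a reset
  for (i in 1:3) st <- choose_strategy(st, rep(1, i + 1L), cfg)
  expect_equal(st$current_strategy, "PSO")
  expect_equal(st$stagnation_count, 0L)
  expect_equal(length(st$strategy_log), 5L)
})

test_that("optimize produces monotone bounded seeded trajectories", {
  cfg <- optimizer_config(bounds = c(-5, 5), seed = 42L, n_iterations = 40L)
  res <- ddtpso_optimize(sphere, 5L, cfg)
  expect_length(res$best_history, 40L)
  expect_true(all(diff(res$best_history) <= 0))
  expect_true(all(res$population$position >= -5 & res$population$position <= 5))
  res2 <- ddtpso_optimize(sphere, 5L, cfg)
  expect_identical(res$best_history, res2$best_history)
  expect_identical(res$best_position, res2$best_position)

  # monotonicity and bounds hold across seeds and objectives
  rast <- benchmark_objective("rastrigin", 3L)$fn
  for (s in 1:5) {
    r <- ddtpso_optimize(rast, 3L,
                         optimizer_config(bounds = c(-5.12, 5.12), seed = s,
                                          n_iterations = 30L))
    expect_true(all(diff(r$best_history) <= 0))
    expect_true(all(abs(r$population$position) <= 5.12))
  }
})

test_that("a constant objective yields a flat history and both strategies", {
  cfg <- optimizer_config(seed = 3L, n_iterations = 30L, swap_patience = 5L)
  res <- ddtpso_optimize(function(x) 1, 3L, cfg)
  expect_true(all(res$best_history == 1))
  expect_length(res$strategy_log, 30L)
  # stagnation forces swaps, so both strategies appear in the log
  expect_setequal(unique(res$strategy_log), c("DTO", "PSO"))
})

test_that("non-finite objective values never displace a finite best", {
  spiky <- function(x) if (x[1] > 0) NaN else sum(x^2)
  res <- ddtpso_optimize(spiky, 2L,
                         optimizer_config(bounds = c(-2, 2), seed = 8L,
                                          n_iterations = 20L))
  expect_true(is.finite(res$best_fitness))
  expect_true(all(is.finite(res$best_history)))
  expect_gt(res$n_nonfinite, 0L)
})

test_that("the fixed-PSO strategy reproduces an independently coded PSO", {
  # independent re-implementation following the same seed discipline
  plain_pso <- function(objective, dim, cfg) {
    set.seed(cfg$seed)
    n <- cfg$n_agents
    lo <- cfg$bounds[1L]; hi <- cfg$bounds[2L]
    x <- lo + matrix(runif(n * dim), n, dim) * (hi - lo)
    v <- matrix(0, n, dim)
    fit <- apply(x, 1L, objective)
    pb <- x; pbf <- fit
    gi <- which.min(pbf); gb <- pb[gi, ]; gbf <- pbf[gi]
    hist <- numeric(cfg$n_iterations)
    for (t in seq_len(cfg$n_iterations)) {
      w <- cfg$inertia_max -
        (cfg$inertia_max - cfg$inertia_min) * (t - 1) / cfg$n_iterations
      r1 <- matrix(runif(n * dim), n, dim)
      r2 <- matrix(runif(n * dim), n, dim)
      v <- w * v + cfg$c1 * r1 * (pb - x) +
        cfg$c2 * r2 * (matrix(gb, n, dim, byrow = TRUE) - x)
      x <- pmin(pmax(x + v, lo), hi)
      fit <- apply(x, 1L, objective)
      imp <- fit < pbf
      pbf[imp] <- fit[imp]; pb[imp, ] <- x[imp, , drop = FALSE]
      gi <- which.min(pbf)
      if (pbf[gi] < gbf) { gbf <- pbf[gi]; gb <- pb[gi, ] }
      hist[t] <- gbf
    }
    list(best_fitness = gbf, best_history = hist)
  }
  cfg <- optimizer_config(bounds = c(-5, 5), seed = 11L, n_iterations = 25L)
  mine <- ddtpso_optimize(sphere, 4L, cfg, strategy = "pso")
  ref <- plain_pso(sphere, 4L, cfg)
  expect_identical(mine$best_history, ref$best_history)
  expect_identical(mine$best_fitness, ref$best_fitness)
  expect_true(all(mine$strategy_log == "PSO"))
})
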