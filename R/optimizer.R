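#' Optimizer configuration
#'
#' Builds the configuration object shared by the continuous optimizers.
#' Defaults follow the study conditions: 10 search agents, 80 iterations,
#' a time-decreasing inertia weight between 0.9 and 0.6, acceleration
#' constants of 2, and a 70% exploration share for the dipper-throated
#' update.
#'
#' @param n_agents Number of search agents (population size), at least 2.
#' @param n_iterations Number of iterations of the main loop.
#' @param bounds Search-space box: a length-2 numeric vector \code{c(low, high)}
#'   recycled over dimensions, or a \code{dim x 2} matrix of per-dimension
#'   bounds. All bounds must be finite.
#' @param inertia_max,inertia_min PSO inertia weight at the first and last
#'   iteration; the schedule decreases linearly in between.
#' @param c1,c2 PSO acceleration constants (cognitive and social).
#' @param exploration_fraction Fraction in (0, 1] of agents taking the
#'   exploratory ("flying") dipper-throated update; the remainder take the
#'   exploitative ("swimming") update.
#' @param swap_patience Number of consecutive stagnant iterations after which
#'   the dynamic controller switches strategy.
#' @param swap_tolerance Minimum decrease of the best-so-far fitness that
#'   counts as an improvement.
#' @param seed Integer seed controlling all randomness of a run.
#' @return An object of class \code{optimizer_config}.
#' @export
optimizer_config <- function(n_agents = 10L, n_iterations = 80L,
                             bounds = c(-5, 5),
                             inertia_max = 0.9, inertia_min = 0.6,
                             c1 = 2, c2 = 2,
                             exploration_fraction = 0.7,
                             swap_patience = 5L, swap_tolerance = 1e-8,
                             seed = 1L) {
  n_agents <- as.integer(n_agents)
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_agents) || n_agents < 2L)
    stop("configuration error: 'n_agents' must be an integer >= 2", call. = FALSE)
  if (is.na(n_iterations) || n_iterations < 1L)
    stop("configuration error: 'n_iterations' must be a positive integer", call. = FALSE)
  if (inertia_min > inertia_max)
    stop("configuration error: 'inertia_min' must not exceed 'inertia_max'", call. = FALSE)
  if (!(exploration_fraction > 0 && exploration_fraction <= 1))
    stop("configuration error: 'exploration_fraction' must be in (0, 1]", call. = FALSE)
  if (swap_patience < 1L)
    stop("configuration error: 'swap_patience' must be >= 1", call. = FALSE)
  structure(list(
    n_agents = n_agents, n_iterations = n_iterations, bounds = bounds,
    inertia_max = inertia_max, inertia_min = inertia_min, c1 = c1, c2 = c2,
    exploration_fraction = exploration_fraction,
    swap_patience = as.integer(swap_patience), swap_tolerance = swap_tolerance,
    seed = as.integer(seed)
  ), class = "optimizer_config")
}

# Expand bounds to a dim x 2 matrix and validate finiteness.
resolve_bounds <- function(bounds, dim) {
  if (is.matrix(bounds)) {
    if (ncol(bounds) != 2L)
      stop("configuration error: bounds matrix must have two columns", call. = FALSE)
    if (nrow(bounds) == 1L) bounds <- bounds[rep(1L, dim), , drop = FALSE]
    if (nrow(bounds) != dim)
      stop("configuration error: bounds matrix rows must match 'dim'", call. = FALSE)
  } else {
    if (length(bounds) != 2L)
      stop("configuration error: bounds must be c(low, high) or a dim x 2 matrix",
           call. = FALSE)
    bounds <- matrix(rep(as.numeric(bounds), each = dim), ncol = 2L)
  }
  if (any(!is.finite(bounds)))
    stop("configuration error: bounds must be finite", call. = FALSE)
  if (any(bounds[, 1L] >= bounds[, 2L]))
    stop("configuration error: each lower bound must be below its upper bound",
         call. = FALSE)
  bounds
}

clip_positions <- function(x, bounds) {
  lo <- matrix(bounds[, 1L], nrow(x), ncol(x), byrow = TRUE)
  hi <- matrix(bounds[, 2L], nrow(x), ncol(x), byrow = TRUE)
  pmin(pmax(x, lo), hi)
}

# Row-wise objective evaluation; non-finite values are flagged and replaced by
# +Inf so the agent can never displace a finite personal best.
evaluate_objective <- function(objective, x) {
  fit <- apply(x, 1L, function(row) {
    val <- objective(row)
    if (!is.numeric(val) || length(val) != 1L) return(NaN)
    val
  })
  bad <- !is.finite(fit)
  fit[bad] <- Inf
  list(fitness = as.numeric(fit), n_nonfinite = sum(bad))
}

#' Initialize a population
#'
#' Draws agent positions uniformly inside the bounds, sets velocities to zero,
#' evaluates all agents, and records personal and global bests.
#'
#' @param config An \code{\link{optimizer_config}}.
#' @param dim Search-space dimensionality, at least 1.
#' @param objective Function mapping a numeric vector of length \code{dim} to a
#'   scalar (minimized).
#' @return A \code{population} object: position/velocity matrices, fitness
#'   vectors, personal and global bests, iteration counter and best-so-far
#'   history.
#' @export
init_population <- function(config, dim, objective) {
  stopifnot(inherits(config, "optimizer_config"))
  dim <- as.integer(dim)
  if (dim < 1L) stop("configuration error: 'dim' must be >= 1", call. = FALSE)
  bounds <- resolve_bounds(config$bounds, dim)
  n <- config$n_agents
  lo <- matrix(bounds[, 1L], n, dim, byrow = TRUE)
  hi <- matrix(bounds[, 2L], n, dim, byrow = TRUE)
  position <- lo + matrix(stats::runif(n * dim), n, dim) * (hi - lo)
  ev <- evaluate_objective(objective, position)
  ibest <- which.min(ev$fitness)
  structure(list(
    position = position,
    velocity = matrix(0, n, dim),
    fitness = ev$fitness,
    pbest_position = position,
    pbest_fitness = ev$fitness,
    gbest_position = position[ibest, ],
    gbest_fitness = ev$fitness[ibest],
    iteration = 0L,
    best_history = numeric(0),
    bounds = bounds,
    n_nonfinite = ev$n_nonfinite
  ), class = "population")
}

# Refresh personal and global bests after a move. Ties keep the incumbent
# (first-found wins), so trajectories are stable under seeds.
refresh_bests <- function(pop, ev) {
  pop$fitness <- ev$fitness
  pop$n_nonfinite <- pop$n_nonfinite + ev$n_nonfinite
  improved <- ev$fitness < pop$pbest_fitness
  pop$pbest_fitness[improved] <- ev$fitness[improved]
  pop$pbest_position[improved, ] <- pop$position[improved, , drop = FALSE]
  ib <- which.min(pop$pbest_fitness)
  if (pop$pbest_fitness[ib] < pop$gbest_fitness) {
    pop$gbest_fitness <- pop$pbest_fitness[ib]
    pop$gbest_position <- pop$pbest_position[ib, ]
  }
  pop
}

#' One particle-swarm update step
#'
#' Applies the classic velocity/position update with a linearly decreasing
#' inertia weight: \code{w(t) = inertia_max - (inertia_max - inertia_min) * t /
#' n_iterations}, evaluated at the population's current iteration counter.
#' Positions are clipped to the bounds after the move.
#'
#' @param pop A \code{population}.
#' @param config An \code{\link{optimizer_config}}.
#' @param objective The objective function being minimized.
#' @param r1,r2 Optional fixed random matrices (agents x dims) replacing the
#'   uniform draws; intended for testing the update rule.
#' @return The updated \code{population}.
#' @export
pso_update <- function(pop, config, objective, r1 = NULL, r2 = NULL) {
  n <- nrow(pop$position); d <- ncol(pop$position)
  w <- config$inertia_max -
    (config$inertia_max - config$inertia_min) * pop$iteration / config$n_iterations
  if (is.null(r1)) r1 <- matrix(stats::runif(n * d), n, d)
  if (is.null(r2)) r2 <- matrix(stats::runif(n * d), n, d)
  gbest <- matrix(pop$gbest_position, n, d, byrow = TRUE)
  pop$velocity <- w * pop$velocity +
    config$c1 * r1 * (pop$pbest_position - pop$position) +
    config$c2 * r2 * (gbest - pop$position)
  pop$position <- clip_positions(pop$position + pop$velocity, pop$bounds)
  refresh_bests(pop, evaluate_objective(objective, pop$position))
}

#' One dipper-throated update step
#'
#' Agents are ranked by current fitness. The worst
#' \code{ceiling(exploration_fraction * n_agents)} agents take the exploratory
#' "flying" velocity update
#' \code{v <- K3*v + K4*r1*(x_best - x) + K5*r2*(x_gbest - x)}; the remaining
#' agents take the exploitative "swimming" update
#' \code{x <- x_best - K1*|K2*x_best - x|}. \code{x_best} is the position of
#' the currently fittest agent. Coefficients are drawn per agent per
#' iteration: \code{K1 = 2*u1*(1 - t/n_iterations)}, \code{K2..K5 = u2..u5},
#' with \code{u_i ~ Uniform(0,1)}. Positions are clipped to bounds.
#'
#' @inheritParams pso_update
#' @param K Optional list with elements \code{K1..K5} (scalars or length
#'   \code{n_agents} vectors) overriding the random coefficient draws; for
#'   testing.
#' @return The updated \code{population}.
#' @export
dto_update <- function(pop, config, objective, K = NULL, r1 = NULL, r2 = NULL) {
  n <- nrow(pop$position); d <- ncol(pop$position)
  ord <- order(pop$fitness)
  n_fly <- min(n, max(1L, ceiling(config$exploration_fraction * n)))
  fly_idx <- ord[seq.int(n - n_fly + 1L, n)]     # worst agents explore
  swim_idx <- setdiff(ord, fly_idx)              # best agents exploit
  xbest <- pop$position[ord[1L], ]

  u <- matrix(stats::runif(5L * n), n, 5L)
  K1 <- 2 * u[, 1L] * (1 - pop$iteration / config$n_iterations)
  K2 <- u[, 2L]; K3 <- u[, 3L]; K4 <- u[, 4L]; K5 <- u[, 5L]
  if (!is.null(K)) {
    if (!is.null(K$K1)) K1 <- rep_len(K$K1, n)
    if (!is.null(K$K2)) K2 <- rep_len(K$K2, n)
    if (!is.null(K$K3)) K3 <- rep_len(K$K3, n)
    if (!is.null(K$K4)) K4 <- rep_len(K$K4, n)
    if (!is.null(K$K5)) K5 <- rep_len(K$K5, n)
  }
  if (is.null(r1)) r1 <- matrix(stats::runif(n * d), n, d)
  if (is.null(r2)) r2 <- matrix(stats::runif(n * d), n, d)

  xb <- matrix(xbest, n, d, byrow = TRUE)
  gb <- matrix(pop$gbest_position, n, d, byrow = TRUE)
  if (length(fly_idx)) {
    i <- fly_idx
    pop$velocity[i, ] <- K3[i] * pop$velocity[i, , drop = FALSE] +
      K4[i] * r1[i, , drop = FALSE] * (xb[i, , drop = FALSE] - pop$position[i, , drop = FALSE]) +
      K5[i] * r2[i, , drop = FALSE] * (gb[i, , drop = FALSE] - pop$position[i, , drop = FALSE])
    pop$position[i, ] <- pop$position[i, , drop = FALSE] + pop$velocity[i, , drop = FALSE]
  }
  if (length(swim_idx)) {
    i <- swim_idx
    pop$position[i, ] <- xb[i, , drop = FALSE] -
      K1[i] * abs(K2[i] * xb[i, , drop = FALSE] - pop$position[i, , drop = FALSE])
  }
  pop$position <- clip_positions(pop$position, pop$bounds)
  refresh_bests(pop, evaluate_objective(objective, pop$position))
}

#' Dynamic strategy controller state
#'
#' @param start Strategy used at the first iteration.
#' @return A \code{strategy_state} with the current strategy, a stagnation
#'   counter and the per-iteration strategy log.
#' @export
strategy_state <- function(start = "DTO") {
  start <- match.arg(start, c("DTO", "PSO"))
  structure(list(current_strategy = start, stagnation_count = 0L,
                 strategy_log = character(0)),
            class = "strategy_state")
}

#' Choose the strategy for the next iteration
#'
#' Stagnation-driven swapping: the controller starts with DTO and keeps the
#' current strategy while the best-so-far fitness improves by more than
#' \code{swap_tolerance}. After \code{swap_patience} consecutive iterations
#' without such an improvement it switches to the other strategy and resets
#' the counter.
#'
#' @param state A \code{\link{strategy_state}}.
#' @param best_history Numeric vector of best-so-far fitness per completed
#'   iteration (may be empty on the initial call).
#' @param config An \code{\link{optimizer_config}}.
#' @return The updated \code{strategy_state}; the chosen strategy is
#'   \code{$current_strategy} and is appended to \code{$strategy_log}.
#' @export
choose_strategy <- function(state, best_history, config) {
  stopifnot(inherits(state, "strategy_state"))
  h <- length(best_history)
  if (h >= 2L) {
    improved <- (best_history[h - 1L] - best_history[h]) > config$swap_tolerance
    if (improved) {
      state$stagnation_count <- 0L
    } else {
      state$stagnation_count <- state$stagnation_count + 1L
      if (state$stagnation_count >= config$swap_patience) {
        state$current_strategy <-
          if (state$current_strategy == "DTO") "PSO" else "DTO"
        state$stagnation_count <- 0L
      }
    }
  }
  state$strategy_log <- c(state$strategy_log, state$current_strategy)
  state
}

#' Run the DDTPSO optimizer
#'
#' Minimizes \code{objective} over the bounded box by iterating population
#' updates, each iteration using the strategy chosen by the dynamic
#' controller (or a fixed strategy for the plain PSO / plain DTO baselines).
#'
#' @param objective Function from a length-\code{dim} numeric vector to a
#'   scalar; minimized. Non-finite returns are treated as worst-possible and
#'   counted in \code{$n_nonfinite}.
#' @param dim Search-space dimensionality.
#' @param config An \code{\link{optimizer_config}}; \code{config$seed} seeds
#'   the whole run.
#' @param strategy \code{"dynamic"} (default, the hybrid), \code{"pso"} or
#'   \code{"dto"} (fixed single-strategy baselines).
#' @return An object of class \code{ddtpso_result}: \code{best_position},
#'   \code{best_fitness}, \code{best_history} (best-so-far per iteration,
#'   non-increasing), \code{strategy_log}, \code{n_nonfinite} and the final
#'   \code{population}.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- ddtpso_optimize(sphere, dim = 5,
#'                        config = optimizer_config(bounds = c(-5, 5), seed = 42))
#' res$best_fitness
#' @export
ddtpso_optimize <- function(objective, dim, config = optimizer_config(),
                            strategy = c("dynamic", "pso", "dto")) {
  strategy <- match.arg(strategy)
  set.seed(config$seed)
  pop <- init_population(config, dim, objective)
  state <- strategy_state(start = if (strategy == "pso") "PSO" else "DTO")
  best_history <- numeric(config$n_iterations)
  for (t in seq_len(config$n_iterations)) {
    if (strategy == "dynamic") {
      state <- choose_strategy(state, best_history[seq_len(t - 1L)], config)
      use <- state$current_strategy
    } else {
      use <- if (strategy == "pso") "PSO" else "DTO"
      state$strategy_log <- c(state$strategy_log, use)
    }
    pop <- if (use == "PSO") pso_update(pop, config, objective)
           else dto_update(pop, config, objective)
    pop$iteration <- t
    best_history[t] <- pop$gbest_fitness
  }
  pop$best_history <- best_history
  structure(list(
    best_position = pop$gbest_position,
    best_fitness = pop$gbest_fitness,
    best_history = best_history,
    strategy_log = state$strategy_log,
    n_nonfinite = pop$n_nonfinite,
    population = pop,
    config = config,
    strategy = strategy
  ), class = "ddtpso_result")
}

#' @export
print.ddtpso_result <- function(x, ...) {
  cat("DDTPSO result (", x$strategy, " strategy)\n", sep = "")
  cat("  best fitness: ", format(x$best_fitness), "\n", sep = "")
  cat("  iterations:   ", length(x$best_history), "\n", sep = "")
  cat("  strategies:   ", paste(rle(x$strategy_log)$values, collapse = " -> "),
      "\n", sep = "")
  invisible(x)
}
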