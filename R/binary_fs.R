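#' Feature-selection configuration
#'
#' Parameters of the binary wrapper selector (bDDTPSO): the slope-10 logistic
#' transfer centered at 0.5 with an inclusive 0.50 binarization threshold,
#' the error/size weighting of the fitness, the KNN assessor, and the
#' continuous optimizer driving the search over the unit box.
#'
#' @param sigmoid_slope Logistic slope (default 10).
#' @param sigmoid_center Logistic center (default 0.5).
#' @param threshold Binarization threshold on the transferred value; the
#'   comparison is inclusive (\code{>=}). Must lie strictly in (0, 1).
#' @param alpha Weight on the classification error in the fitness
#'   \code{alpha * error + (1 - alpha) * selected_fraction}; in (0, 1].
#' @param knn_k Neighbourhood size of the KNN assessor; odd, at least 1.
#' @param optimizer An \code{\link{optimizer_config}} for the continuous
#'   search. Its bounds are fixed to the unit box internally.
#' @param n_runs Default number of independent runs in experiments.
#' @return An object of class \code{fs_config}.
#' @export
fs_config <- function(sigmoid_slope = 10, sigmoid_center = 0.5,
                      threshold = 0.50, alpha = 0.99, knn_k = 5L,
                      optimizer = optimizer_config(bounds = c(0, 1)),
                      n_runs = 20L) {
  if (!(threshold > 0 && threshold < 1))
    stop("configuration error: 'threshold' must be in (0, 1)", call. = FALSE)
  if (!(alpha > 0 && alpha <= 1))
    stop("configuration error: 'alpha' must be in (0, 1]", call. = FALSE)
  knn_k <- as.integer(knn_k)
  if (knn_k < 1L || knn_k %% 2L == 0L)
    stop("configuration error: 'knn_k' must be odd and >= 1", call. = FALSE)
  structure(list(sigmoid_slope = sigmoid_slope, sigmoid_center = sigmoid_center,
                 threshold = threshold, alpha = alpha, knn_k = knn_k,
                 optimizer = optimizer, n_runs = as.integer(n_runs)),
            class = "fs_config")
}

#' Construct a feature mask
#'
#' @param bits 0/1 (or logical) vector; 1 means the feature is selected.
#' @return An object of class \code{feature_mask}: \code{bits},
#'   \code{selected_count}, \code{selected_fraction}.
#' @export
feature_mask <- function(bits) {
  bits <- as.integer(as.logical(bits))
  structure(list(bits = bits, selected_count = sum(bits),
                 selected_fraction = sum(bits) / length(bits)),
            class = "feature_mask")
}

#' Sigmoid transfer function
#'
#' Maps a continuous solution component to (0, 1) via
#' \code{1 / (1 + exp(-slope * (x - center)))}; strictly increasing, equal to
#' 1/2 at the center, saturating at the extremes.
#'
#' @param component Numeric vector of solution components.
#' @param config An \code{\link{fs_config}} (only the slope and center are
#'   used).
#' @return Numeric vector of values strictly in (0, 1).
#' @export
sigmoid_transfer <- function(component, config = fs_config()) {
  1 / (1 + exp(-config$sigmoid_slope * (component - config$sigmoid_center)))
}

#' Binarize a continuous solution into a feature mask
#'
#' Each component is passed through \code{\link{sigmoid_transfer}} and the
#' bit is set when the transferred value is greater than or equal to the
#' threshold (inclusive comparison, so a component exactly at the sigmoid
#' center maps to 1 at the default threshold 0.50).
#'
#' @param solution Numeric vector (a point of the continuous search space).
#' @param config An \code{\link{fs_config}}.
#' @return A \code{\link{feature_mask}}.
#' @export
binarize <- function(solution, config = fs_config()) {
  feature_mask(sigmoid_transfer(solution, config) >= config$threshold)
}

#' Wrapper fitness of a feature mask
#'
#' The weighted sum \code{alpha * error + (1 - alpha) * selected_fraction},
#' where the error is the KNN misclassification rate on the validation split
#' using only the selected features. An all-zero mask cannot be assessed and
#' receives a \code{+Inf} sentinel so it is never chosen as best.
#'
#' @param mask A \code{\link{feature_mask}} of length equal to the feature
#'   count.
#' @param dataset A \code{\link{feature_dataset}} (unused when \code{split}
#'   already carries the subsets; kept for contract clarity).
#' @param split A list with \code{train} and \code{valid}
#'   \code{feature_dataset}s, as produced by
#'   \code{\link{split_train_valid_test}}.
#' @param config An \code{\link{fs_config}}.
#' @return Scalar fitness (minimized), or \code{+Inf} for the empty mask.
#' @export
fs_fitness <- function(mask, dataset = NULL, split, config = fs_config()) {
  stopifnot(inherits(mask, "feature_mask"))
  if (mask$selected_count < 1L) return(Inf)
  err <- knn_classify_error(split$train, split$valid, mask, config$knn_k)
  config$alpha * err + (1 - config$alpha) * mask$selected_fraction
}

#' Select features with the binary DDTPSO wrapper
#'
#' Runs the continuous DDTPSO over the unit box \eqn{[0,1]^d}; every candidate
#' is binarized through the sigmoid transfer at evaluation time (the
#' continuous population is never overwritten by bits) and scored by the KNN
#' wrapper fitness on the train/validation split. The best binary solution
#' seen anywhere during the run is returned.
#'
#' @param dataset A \code{\link{feature_dataset}} with at least 2 classes and
#'   2 features.
#' @param config An \code{\link{fs_config}}; \code{config$optimizer$seed}
#'   makes the run deterministic.
#' @param split Optional pre-computed split (as from
#'   \code{\link{split_train_valid_test}}); by default the dataset is split
#'   with the optimizer seed.
#' @return An object of class \code{fs_run_result}: \code{best_mask},
#'   \code{best_fitness}, \code{error_rate} (validation error of the best
#'   mask), \code{fitness_history} (best-so-far, non-increasing),
#'   \code{n_empty_masks} (evaluations hitting the all-zero sentinel) and
#'   \code{seed}.
#' @export
select_features <- function(dataset, config = fs_config(), split = NULL) {
  stopifnot(inherits(dataset, "feature_dataset"))
  d <- ncol(dataset$features)
  if (d < 2L) stop("configuration error: need at least 2 features", call. = FALSE)
  if (is.null(split)) split <- split_train_valid_test(dataset, config$optimizer$seed)
  opt_cfg <- config$optimizer
  opt_cfg$bounds <- c(0, 1)

  tracker <- new.env(parent = emptyenv())
  tracker$best_fitness <- Inf
  tracker$best_bits <- rep(1L, d)
  tracker$n_empty <- 0L
  objective <- function(v) {
    mask <- binarize(v, config)
    fit <- fs_fitness(mask, dataset, split, config)
    if (is.infinite(fit)) tracker$n_empty <- tracker$n_empty + 1L
    if (fit < tracker$best_fitness) {
      tracker$best_fitness <- fit
      tracker$best_bits <- mask$bits
    }
    fit
  }
  res <- ddtpso_optimize(objective, d, opt_cfg, strategy = "dynamic")
  best_mask <- feature_mask(tracker$best_bits)
  structure(list(
    best_mask = best_mask,
    best_fitness = tracker$best_fitness,
    error_rate = knn_classify_error(split$train, split$valid, best_mask,
                                    config$knn_k),
    fitness_history = res$best_history,
    strategy_log = res$strategy_log,
    n_empty_masks = tracker$n_empty,
    seed = opt_cfg$seed
  ), class = "fs_run_result")
}

#' @export
print.fs_run_result <- function(x, ...) {
  cat("bDDTPSO feature-selection run (seed ", x$seed, ")\n", sep = "")
  cat("  selected ", x$best_mask$selected_count, "/",
      length(x$best_mask$bits), " features; fitness ",
      format(round(x$best_fitness, 4)), "; validation error ",
      format(round(x$error_rate, 4)), "\n", sep = "")
  invisible(x)
}

#' Run a multi-method feature-selection experiment
#'
#' Executes \code{n_runs} independent seeded runs of each method and returns
#' the per-run results, ready for \code{\link{fs_run_statistics}} and the
#' statistical harness. Every method x run cell receives a globally distinct
#' seed derived from \code{seed_base}.
#'
#' @param dataset A \code{\link{feature_dataset}}.
#' @param methods Named list of functions \code{function(dataset, seed)}
#'   returning an \code{fs_run_result}-like list (see
#'   \code{\link{fs_method_ddtpso}} and friends).
#' @param n_runs Runs per method.
#' @param seed_base Integer base seed.
#' @return Named list (per method) of lists of run results.
#' @export
run_fs_experiment <- function(dataset, methods, n_runs = 20L, seed_base = 1L) {
  stopifnot(length(methods) >= 1L, !is.null(names(methods)))
  offset <- 0L
  out <- lapply(methods, function(method) {
    runs <- lapply(seq_len(n_runs), function(r) {
      seed <- seed_base + offset + r - 1L
      method(dataset, seed)
    })
    offset <<- offset + n_runs
    runs
  })
  names(out) <- names(methods)
  out
}

#' Ready-made feature-selection methods for experiments
#'
#' Method wrappers with the \code{function(dataset, seed)} signature expected
#' by \code{\link{run_fs_experiment}}: the dynamic hybrid (bDDTPSO), the
#' fixed single-strategy baselines (bPSO, bDTO), and a random-mask control
#' that evaluates the same number of uniformly drawn masks as the wrapper
#' evaluates candidates.
#'
#' @param config An \code{\link{fs_config}} template; the seed is overridden
#'   per run.
#' @return A function \code{function(dataset, seed)} returning an
#'   \code{fs_run_result}.
#' @export
fs_method_ddtpso <- function(config = fs_config()) {
  function(dataset, seed) {
    config$optimizer$seed <- as.integer(seed)
    select_features(dataset, config)
  }
}

fs_method_fixed <- function(config, strategy) {
  force(strategy)
  function(dataset, seed) {
    config$optimizer$seed <- as.integer(seed)
    d <- ncol(dataset$features)
    split <- split_train_valid_test(dataset, seed)
    opt_cfg <- config$optimizer
    opt_cfg$bounds <- c(0, 1)
    tracker <- new.env(parent = emptyenv())
    tracker$best_fitness <- Inf
    tracker$best_bits <- rep(1L, d)
    objective <- function(v) {
      mask <- binarize(v, config)
      fit <- fs_fitness(mask, dataset, split, config)
      if (fit < tracker$best_fitness) {
        tracker$best_fitness <- fit
        tracker$best_bits <- mask$bits
      }
      fit
    }
    res <- ddtpso_optimize(objective, d, opt_cfg, strategy = strategy)
    best_mask <- feature_mask(tracker$best_bits)
    structure(list(best_mask = best_mask, best_fitness = tracker$best_fitness,
                   error_rate = knn_classify_error(split$train, split$valid,
                                                   best_mask, config$knn_k),
                   fitness_history = res$best_history, seed = seed),
              class = "fs_run_result")
  }
}

#' @rdname fs_method_ddtpso
#' @export
fs_method_pso <- function(config = fs_config()) fs_method_fixed(config, "pso")

#' @rdname fs_method_ddtpso
#' @export
fs_method_dto <- function(config = fs_config()) fs_method_fixed(config, "dto")

#' @rdname fs_method_ddtpso
#' @export
fs_method_random <- function(config = fs_config()) {
  function(dataset, seed) {
    set.seed(seed)
    d <- ncol(dataset$features)
    split <- split_train_valid_test(dataset, seed)
    n_eval <- config$optimizer$n_agents * (config$optimizer$n_iterations + 1L)
    best_fit <- Inf
    best_bits <- rep(1L, d)
    history <- numeric(0)
    for (i in seq_len(n_eval)) {
      mask <- feature_mask(stats::runif(d) >= 0.5)
      fit <- fs_fitness(mask, dataset, split, config)
      if (fit < best_fit) { best_fit <- fit; best_bits <- mask$bits }
      history <- c(history, best_fit)
    }
    best_mask <- feature_mask(best_bits)
    structure(list(best_mask = best_mask, best_fitness = best_fit,
                   error_rate = knn_classify_error(split$train, split$valid,
                                                   best_mask, config$knn_k),
                   fitness_history = history, seed = seed),
              class = "fs_run_result")
  }
}

#' Exhaustive-search optimum over all non-empty masks
#'
#' Brute-force reference for small feature counts: evaluates the wrapper
#' fitness of every one of the \eqn{2^d - 1} non-empty masks and returns the
#' best. Intended as an oracle for validating the stochastic selector
#' (practical for d up to ~15).
#'
#' @param dataset A \code{\link{feature_dataset}} with \code{d <= 20}.
#' @param config An \code{\link{fs_config}}.
#' @param split A split as from \code{\link{split_train_valid_test}}.
#' @return List: \code{best_mask}, \code{best_fitness}, \code{n_evaluated}.
#' @export
exhaustive_fs_optimum <- function(dataset, config = fs_config(), split) {
  d <- ncol(dataset$features)
  if (d > 20L) stop("exhaustive search is limited to 20 features", call. = FALSE)
  best_fit <- Inf; best_bits <- NULL
  for (code in seq_len(2L^d - 1L)) {
    bits <- as.integer(intToBits(code)[seq_len(d)] == 1L)
    mask <- feature_mask(bits)
    fit <- fs_fitness(mask, dataset, split, config)
    if (fit < best_fit) { best_fit <- fit; best_bits <- bits }
  }
  list(best_mask = feature_mask(best_bits), best_fitness = best_fit,
       n_evaluated = 2L^d - 1L)
}
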