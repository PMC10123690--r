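# Shared fixtures, all generated in code.

# The standard synthetic dataset used across modules (200 samples, 5
# informative + 3 redundant + 12 noise features, 2 classes, separation 3).
standard_dataset <- function() gen_feature_dataset(synthetic_spec())

# The standard dataset restricted to its first 10 columns (for exhaustive
# mask oracles).
standard_dataset_d10 <- function() {
  g <- standard_dataset()
  ds <- g$dataset
  ds$features <- ds$features[, 1:10]
  ds$feature_names <- ds$feature_names[1:10]
  ds
}

# Two well-separated Gaussian classes: KNN error is essentially zero.
separable_dataset <- function(n = 60L, d = 4L, sep = 8, seed = 99L) {
  set.seed(seed)
  lab <- rep(c("a", "b"), length.out = n)
  X <- matrix(rnorm(n * d), n, d) + sep * (lab == "b")
  feature_dataset(X, lab)
}

# A small asymmetric square test image (no symmetry of the square fixes it).
asym_image <- function(n = 5L, seed = 3L) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

# Build a population by hand for update-rule unit tests.
manual_population <- function(position, velocity, objective, config) {
  n <- nrow(position); d <- ncol(position)
  fit <- apply(position, 1L, objective)
  ib <- which.min(fit)
  structure(list(
    position = position, velocity = velocity, fitness = fit,
    pbest_position = position, pbest_fitness = fit,
    gbest_position = position[ib, ], gbest_fitness = fit[ib],
    iteration = 0L, best_history = numeric(0),
    bounds = ddtpso:::resolve_bounds(config$bounds, d), n_nonfinite = 0L
  ), class = "population")
}
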