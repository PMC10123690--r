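#' Specification of a synthetic feature table
#'
#' Describes a class-labelled continuous feature table emulating deep
#' (global-average-pooling) image features: an informative block of
#' class-conditional Gaussians, a redundant block of noisy linear combinations
#' of the informative columns, and a block of pure-noise columns. The default
#' values define the standard fixture used throughout the package's
#' validation: 200 samples, 5 informative + 3 redundant + 12 noise features,
#' 2 classes, class separation 3 within-class standard deviations, seed 7.
#'
#' @param n_samples Number of rows.
#' @param n_informative,n_redundant,n_noise Column counts of the three blocks;
#'   their sum (the total dimensionality) must be at least 2.
#' @param n_classes Number of classes, at least 2.
#' @param class_separation Between-class mean shift of each informative
#'   feature, in units of the within-class standard deviation (which is 1).
#' @param redundancy_noise_sd Standard deviation of the Gaussian noise added
#'   to each redundant column.
#' @param seed Integer seed.
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_samples = 200L, n_informative = 5L,
                           n_redundant = 3L, n_noise = 12L, n_classes = 2L,
                           class_separation = 3, redundancy_noise_sd = 0.1,
                           seed = 7L) {
  d <- n_informative + n_redundant + n_noise
  if (d < 2L) stop("configuration error: total feature count must be >= 2", call. = FALSE)
  if (n_classes < 2L) stop("configuration error: 'n_classes' must be >= 2", call. = FALSE)
  if (n_informative < 1L) stop("configuration error: need >= 1 informative feature", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 n_noise = as.integer(n_noise),
                 n_classes = as.integer(n_classes),
                 class_separation = class_separation,
                 redundancy_noise_sd = redundancy_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic feature dataset with known ground truth
#'
#' Informative columns are class-conditional Gaussians with unit within-class
#' standard deviation and class means at \code{(k - 1) * class_separation}
#' times a random sign per column. Redundant columns are random linear
#' combinations (unit-norm weights) of the informative block plus Gaussian
#' noise. Noise columns are standard normal, independent of the label. Class
#' sizes are balanced to within one sample. Columns are shuffled with a
#' recorded permutation so selection methods cannot exploit ordering.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return A list: \code{dataset} (a \code{\link{feature_dataset}}),
#'   \code{informative_idx}, \code{redundant_idx}, \code{noise_idx} (column
#'   positions after shuffling) and \code{permutation} (the applied column
#'   order).
#' @export
gen_feature_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  d <- spec$n_informative + spec$n_redundant + spec$n_noise
  classes <- paste0("class", seq_len(spec$n_classes))
  labels <- factor(rep_len(classes, n), levels = classes)
  labels <- labels[sample.int(n)]

  signs <- sample(c(-1, 1), spec$n_informative, replace = TRUE)
  k <- as.integer(labels)
  informative <- matrix(stats::rnorm(n * spec$n_informative), n, spec$n_informative)
  shift <- outer(k - 1L, signs * spec$class_separation)
  informative <- informative + shift

  redundant <- NULL
  if (spec$n_redundant > 0L) {
    w <- matrix(stats::rnorm(spec$n_informative * spec$n_redundant),
                spec$n_informative, spec$n_redundant)
    w <- sweep(w, 2L, sqrt(colSums(w^2)), "/")
    redundant <- informative %*% w +
      matrix(stats::rnorm(n * spec$n_redundant, sd = spec$redundancy_noise_sd),
             n, spec$n_redundant)
  }
  noise <- if (spec$n_noise > 0L)
    matrix(stats::rnorm(n * spec$n_noise), n, spec$n_noise) else NULL

  X <- cbind(informative, redundant, noise)
  block <- rep(c("inf", "red", "noi"),
               c(spec$n_informative, spec$n_redundant, spec$n_noise))
  perm <- sample.int(d)
  X <- X[, perm, drop = FALSE]
  block <- block[perm]
  colnames(X) <- sprintf("f%02d", seq_len(d))

  list(dataset = feature_dataset(X, labels),
       informative_idx = which(block == "inf"),
       redundant_idx = which(block == "red"),
       noise_idx = which(block == "noi"),
       permutation = perm)
}

#' Generate synthetic grayscale images grouped by class
#'
#' Each image is a sum of anisotropic Gaussian blobs on a low-level noise
#' floor; blob count and dominant orientation depend on the class so that the
#' classes are visually distinct and the images are asymmetric under flips
#' and rotation. Intensities are scaled to [0, 1]. Deterministic under the
#' seed.
#'
#' @param class_counts Named or unnamed positive integer vector of images per
#'   class (unnamed vectors get classes \code{class1, class2, ...}).
#' @param height,width Image size in pixels.
#' @param seed Integer seed.
#' @return A named list (one element per class) of lists of numeric matrices.
#' @export
gen_synthetic_images <- function(class_counts, height = 64L, width = 64L,
                                 seed = 1L) {
  if (any(class_counts < 1L)) stop("class counts must be positive", call. = FALSE)
  if (is.null(names(class_counts)))
    names(class_counts) <- paste0("class", seq_along(class_counts))
  set.seed(seed)
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  out <- lapply(seq_along(class_counts), function(ci) {
    n_blobs <- ci + 2L
    theta <- (ci - 1L) * pi / length(class_counts) + pi / 7
    lapply(seq_len(class_counts[ci]), function(j) {
      img <- matrix(stats::runif(height * width, 0, 0.05), height, width)
      for (b in seq_len(n_blobs)) {
        cy <- stats::runif(1, 0.15, 0.85) * height
        cx <- stats::runif(1, 0.15, 0.85) * width
        s1 <- stats::runif(1, 0.04, 0.10) * height
        s2 <- stats::runif(1, 0.12, 0.22) * width
        u <- (rows - cy) * cos(theta) + (cols - cx) * sin(theta)
        v <- -(rows - cy) * sin(theta) + (cols - cx) * cos(theta)
        img <- img + exp(-(u^2 / (2 * s1^2) + v^2 / (2 * s2^2)))
      }
      img / max(img)
    })
  })
  names(out) <- names(class_counts)
  out
}

#' Benchmark objective functions
#'
#' Standard continuous test functions with a known global minimum, used to
#' validate the optimizers.
#'
#' @param name One of \code{"sphere"}, \code{"rastrigin"},
#'   \code{"rosenbrock"}.
#' @param dim Dimensionality, at least 1.
#' @return A list: \code{fn} (the objective), \code{optimum_position},
#'   \code{optimum_value} (always 0), and conventional \code{bounds}.
#' @export
benchmark_objective <- function(name, dim) {
  dim <- as.integer(dim)
  if (dim < 1L) stop("'dim' must be >= 1", call. = FALSE)
  switch(name,
    sphere = list(
      fn = function(x) sum(x^2),
      optimum_position = rep(0, dim), optimum_value = 0, bounds = c(-5.12, 5.12)),
    rastrigin = list(
      fn = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
      optimum_position = rep(0, dim), optimum_value = 0, bounds = c(-5.12, 5.12)),
    rosenbrock = list(
      fn = function(x) {
        if (length(x) == 1L) return((1 - x)^2)
        sum(100 * (x[-1] - x[-length(x)]^2)^2 + (1 - x[-length(x)])^2)
      },
      optimum_position = rep(1, dim), optimum_value = 0, bounds = c(-2.048, 2.048)),
    stop("unknown benchmark objective: ", name, call. = FALSE)
  )
}
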