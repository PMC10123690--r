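#' Hyperparameter search-space definition
#'
#' A hyperparameter space is a list of parameter specifications, each created
#' with \code{hyperparam}. The space defines a deterministic decode from the
#' unit box \eqn{[0,1]^p} to a named hyperparameter set, which the optimizer
#' searches.
#'
#' @param name Parameter name.
#' @param type \code{"continuous"} (interval, optionally log-scaled),
#'   \code{"integer_grid"} or \code{"categorical"} (decoded by index binning
#'   over \code{values}).
#' @param low,high Interval ends for continuous parameters.
#' @param values Grid / category values for the other types.
#' @param log Log-scale interpolation for continuous parameters.
#' @return A \code{hyperparam} specification.
#' @export
hyperparam <- function(name, type = c("continuous", "integer_grid", "categorical"),
                       low = NULL, high = NULL, values = NULL, log = FALSE) {
  type <- match.arg(type)
  if (type == "continuous") {
    stopifnot(is.numeric(low), is.numeric(high), low < high)
    if (log && low <= 0) stop("log-scaled parameters need low > 0", call. = FALSE)
  } else {
    stopifnot(length(values) >= 1L)
  }
  structure(list(name = name, type = type, low = low, high = high,
                 values = values, log = log), class = "hyperparam")
}

#' Decode a unit-box point into a hyperparameter set
#'
#' Continuous parameters interpolate linearly (or log-linearly) between their
#' ends, so coordinate 0 maps to \code{low} and 1 to \code{high}. Grid and
#' categorical parameters bin the coordinate into equal-width bins by
#' floor-scaling, clamped so coordinate 1 maps to the last element.
#'
#' @param vector Numeric vector in \eqn{[0,1]^p}, one coordinate per
#'   parameter.
#' @param space List of \code{\link{hyperparam}} specifications.
#' @return Named list of decoded values.
#' @export
decode_hyperparameters <- function(vector, space) {
  if (length(vector) != length(space))
    stop("coordinate vector length must equal the space dimension", call. = FALSE)
  v <- pmin(pmax(vector, 0), 1)
  out <- lapply(seq_along(space), function(i) {
    p <- space[[i]]
    if (p$type == "continuous") {
      if (p$log) exp(log(p$low) + v[i] * (log(p$high) - log(p$low)))
      else p$low + v[i] * (p$high - p$low)
    } else {
      m <- length(p$values)
      p$values[[min(floor(v[i] * m) + 1L, m)]]
    }
  })
  names(out) <- vapply(space, `[[`, character(1L), "name")
  out
}

#' Default hyperparameter space for the built-in MLP classifier
#'
#' Hidden-layer width (integer grid), weight-decay strength (log-continuous)
#' and the training iteration cap (integer grid) of the
#' \code{\link{make_mlp_classifier}} stand-in.
#'
#' @return A list of \code{\link{hyperparam}} specifications.
#' @export
default_mlp_space <- function() {
  list(hyperparam("hidden_width", "integer_grid", values = c(2L, 4L, 8L, 16L)),
       hyperparam("decay", "continuous", low = 1e-4, high = 1, log = TRUE),
       hyperparam("maxit", "integer_grid", values = c(50L, 100L, 200L)))
}

#' Default classifier factory for tuning
#'
#' Builds an MLP classifier from a decoded hyperparameter set; any decoded
#' names matching \code{\link{make_mlp_classifier}} arguments are passed
#' through.
#'
#' @param params Named list of decoded hyperparameters.
#' @return A classifier object (\code{list(fit, predict, spec)}).
#' @export
mlp_classifier_factory <- function(params) {
  do.call(make_mlp_classifier,
          params[names(params) %in%
                   names(formals(make_mlp_classifier))])
}

#' Tune a classifier's hyperparameters with DDTPSO
#'
#' Minimizes the validation error of the classifier built by
#' \code{classifier_factory} over the unit box, decoding each candidate with
#' \code{\link{decode_hyperparameters}}. Training failures are caught and
#' scored as worst-possible. The best decoded configuration, its validation
#' error, the optimizer history and a held-out test-set metrics report are
#' returned.
#'
#' @param dataset A \code{\link{feature_dataset}}; split into stratified
#'   train/validation/test thirds with the optimizer seed.
#' @param mask Optional \code{\link{feature_mask}} restricting the features.
#' @param space Hyperparameter space (list of \code{\link{hyperparam}}).
#' @param optimizer_config An \code{\link{optimizer_config}}; its bounds are
#'   fixed to the unit box internally.
#' @param classifier_factory Function from a decoded hyperparameter set to a
#'   classifier object.
#' @return An object of class \code{tuned_model_result}:
#'   \code{best_hyperparams}, \code{best_position},
#'   \code{validation_error}, \code{history} (best-so-far, non-increasing),
#'   \code{test_metrics}, \code{n_failures}.
#' @export
tune_classifier <- function(dataset, mask = NULL, space = default_mlp_space(),
                            optimizer_config = ddtpso::optimizer_config(
                              n_agents = 5L, n_iterations = 15L, seed = 1L),
                            classifier_factory = mlp_classifier_factory) {
  stopifnot(inherits(dataset, "feature_dataset"))
  sel <- mask_to_logical(mask, ncol(dataset$features))
  ds <- dataset
  ds$features <- ds$features[, sel, drop = FALSE]
  ds$feature_names <- ds$feature_names[sel]
  split <- split_train_valid_test(ds, optimizer_config$seed)

  n_failures <- 0L
  objective <- function(v) {
    params <- decode_hyperparameters(v, space)
    err <- tryCatch({
      clf <- classifier_factory(params)
      model <- clf$fit(split$train)
      pred <- clf$predict(model, split$valid)
      mean(pred != split$valid$labels)
    }, error = function(e) {
      n_failures <<- n_failures + 1L
      Inf
    })
    err
  }
  cfg <- optimizer_config
  cfg$bounds <- c(0, 1)
  res <- ddtpso_optimize(objective, length(space), cfg, strategy = "dynamic")
  best_params <- decode_hyperparameters(res$best_position, space)
  clf <- classifier_factory(best_params)
  model <- clf$fit(split$train)
  pred <- clf$predict(model, split$test)
  total <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (cl in ds$class_names) {
    one <- confusion_counts(split$test$labels, pred, positive_label = cl)
    total <- total + unlist(one[c("TP", "TN", "FP", "FN")])
  }
  structure(list(
    best_hyperparams = best_params,
    best_position = res$best_position,
    validation_error = res$best_fitness,
    history = res$best_history,
    test_metrics = classification_metrics(
      confusion_counts_object(total["TP"], total["TN"], total["FP"], total["FN"])),
    test_accuracy = mean(pred == split$test$labels),
    n_failures = n_failures
  ), class = "tuned_model_result")
}
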