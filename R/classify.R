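#' Construct a feature dataset
#'
#' The unit of selection and classification: a numeric sample-by-feature
#' matrix with a categorical label per row.
#'
#' @param features Numeric matrix (or coercible data frame), samples in rows.
#' @param labels Vector or factor of class labels, one per row.
#' @return An object of class \code{feature_dataset} with elements
#'   \code{features}, \code{labels}, \code{feature_names}, \code{class_names}.
#' @export
feature_dataset <- function(features, labels) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.numeric(features)) stop("'features' must be numeric", call. = FALSE)
  if (any(!is.finite(features)))
    stop("'features' contains non-finite entries", call. = FALSE)
  labels <- droplevels(as.factor(labels))
  if (length(labels) != nrow(features))
    stop("'labels' length must equal the number of rows", call. = FALSE)
  if (nlevels(labels) < 2L)
    stop("configuration error: dataset must contain at least 2 classes", call. = FALSE)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("f%02d", seq_len(ncol(features)))
  structure(list(features = features, labels = labels,
                 feature_names = colnames(features),
                 class_names = levels(labels)),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat("feature_dataset: ", nrow(x$features), " samples x ",
      ncol(x$features), " features, classes: ",
      paste(sprintf("%s (%d)", x$class_names, table(x$labels)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

subset_dataset <- function(dataset, idx) {
  out <- dataset
  out$features <- dataset$features[idx, , drop = FALSE]
  out$labels <- dataset$labels[idx]
  out
}

# Deterministic stratified partition of indices into `parts` near-equal folds.
stratified_folds <- function(labels, parts) {
  fold <- integer(length(labels))
  offset <- 0L
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    # rotate fold numbering across classes so remainders spread evenly
    f <- ((seq_along(idx) - 1L + offset) %% parts) + 1L
    fold[idx] <- f
    offset <- (offset + length(idx)) %% parts
  }
  fold
}

#' Split a dataset into stratified train/validation/test thirds
#'
#' Equal random thirds (within one sample per class), disjoint, covering the
#' dataset. The validation third is the one used when computing wrapper
#' fitness; the test third is held out for final reports.
#'
#' @param dataset A \code{\link{feature_dataset}}.
#' @param seed Integer seed.
#' @return A list with \code{train}, \code{valid}, \code{test}
#'   (\code{feature_dataset}s) and \code{indices} (list of the three index
#'   vectors).
#' @export
split_train_valid_test <- function(dataset, seed) {
  stopifnot(inherits(dataset, "feature_dataset"))
  counts <- table(dataset$labels)
  if (any(counts < 3L))
    stop("class too small to stratify into thirds: ",
         names(counts)[which.min(counts)], call. = FALSE)
  set.seed(seed)
  fold <- stratified_folds(dataset$labels, 3L)
  idx <- list(train = which(fold == 1L), valid = which(fold == 2L),
              test = which(fold == 3L))
  list(train = subset_dataset(dataset, idx$train),
       valid = subset_dataset(dataset, idx$valid),
       test = subset_dataset(dataset, idx$test),
       indices = idx)
}

# Standardize eval features by train column mean/sd (sd 0 -> 1).
standardize_pair <- function(train_x, eval_x) {
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(train = sweep(sweep(train_x, 2L, mu), 2L, sdv, "/"),
       eval = sweep(sweep(eval_x, 2L, mu), 2L, sdv, "/"))
}

# Squared Euclidean distances between rows of a (n_a x d) and b (n_b x d).
sq_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' K-nearest-neighbour classification error
#'
#' Classifies each evaluation sample by majority vote among its \code{k}
#' nearest training samples in standardized Euclidean distance (mean/sd
#' fitted on the training split only), restricted to the features selected by
#' \code{mask}. Vote ties are broken deterministically in favour of the tied
#' class with the nearest neighbour.
#'
#' @param train,eval \code{\link{feature_dataset}}s sharing a feature space.
#' @param mask A \code{\link{feature_mask}}, a 0/1 vector, or \code{NULL} for
#'   all features; must select at least one feature.
#' @param k Neighbourhood size; must not exceed the training-set size.
#' @return The misclassification fraction in [0, 1].
#' @export
knn_classify_error <- function(train, eval, mask = NULL, k = 5L) {
  pred <- knn_predict(train, eval, mask, k)
  mean(pred != eval$labels)
}

# Internal KNN prediction used by both the error and the pipeline reports.
knn_predict <- function(train, eval, mask = NULL, k = 5L) {
  sel <- mask_to_logical(mask, ncol(train$features))
  if (!any(sel)) stop("mask selects no features", call. = FALSE)
  if (k > nrow(train$features))
    stop("'k' exceeds the training-set size", call. = FALSE)
  z <- standardize_pair(train$features[, sel, drop = FALSE],
                        eval$features[, sel, drop = FALSE])
  d2 <- sq_dist(z$eval, z$train)
  lab <- train$labels
  pred <- vapply(seq_len(nrow(d2)), function(i) {
    nn <- order(d2[i, ])[seq_len(k)]
    votes <- table(lab[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    # tie: the tied class owning the closest neighbour wins
    for (j in nn) if (as.character(lab[j]) %in% top) return(as.character(lab[j]))
    top[1L]
  }, character(1L))
  factor(pred, levels = levels(eval$labels))
}

mask_to_logical <- function(mask, d) {
  if (is.null(mask)) return(rep(TRUE, d))
  bits <- if (inherits(mask, "feature_mask")) mask$bits else mask
  if (length(bits) != d)
    stop("mask length does not match the feature count", call. = FALSE)
  as.logical(bits)
}

#' Stratified k-fold evaluation of a classifier
#'
#' Partitions the dataset into \code{k} stratified folds (sizes within one),
#' trains the classifier on \code{k - 1} folds and predicts the held-out fold,
#' cycling through all folds. One-vs-rest confusion counts are accumulated
#' over classes and folds by summation before metrics are computed
#' (micro-averaging).
#'
#' @param dataset A \code{\link{feature_dataset}}; every class needs at least
#'   \code{k} samples.
#' @param mask Feature mask (or \code{NULL} for all features).
#' @param classifier A classifier object as returned by
#'   \code{\link{make_knn_classifier}} or \code{\link{make_mlp_classifier}}:
#'   a list with \code{fit(train_dataset)} returning a model and
#'   \code{predict(model, eval_dataset)} returning a label factor.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return A list: \code{metrics} (a \code{metrics_report} from the summed
#'   counts), \code{counts} (aggregated \code{confusion_counts}),
#'   \code{per_fold} (list of per-fold counts), \code{accuracy} (plain
#'   multiclass accuracy over all held-out predictions).
#' @export
kfold_evaluate <- function(dataset, mask = NULL, classifier = make_knn_classifier(),
                           k = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "feature_dataset"))
  counts <- table(dataset$labels)
  if (any(counts < k))
    stop("class too small for ", k, "-fold stratification: ",
         names(counts)[which.min(counts)], call. = FALSE)
  set.seed(seed)
  fold <- stratified_folds(dataset$labels, k)
  sel <- mask_to_logical(mask, ncol(dataset$features))
  total <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  per_fold <- vector("list", k)
  n_correct <- 0L
  for (f in seq_len(k)) {
    tr <- subset_dataset(dataset, which(fold != f))
    te <- subset_dataset(dataset, which(fold == f))
    tr$features <- tr$features[, sel, drop = FALSE]
    te$features <- te$features[, sel, drop = FALSE]
    model <- classifier$fit(tr)
    pred <- classifier$predict(model, te)
    n_correct <- n_correct + sum(pred == te$labels)
    cc <- c(TP = 0, TN = 0, FP = 0, FN = 0)
    for (cl in dataset$class_names) {
      one <- confusion_counts(te$labels, pred, positive_label = cl)
      cc <- cc + unlist(one[c("TP", "TN", "FP", "FN")])
    }
    per_fold[[f]] <- cc
    total <- total + cc
  }
  agg <- confusion_counts_object(total["TP"], total["TN"], total["FP"], total["FN"])
  list(metrics = classification_metrics(agg), counts = agg, per_fold = per_fold,
       accuracy = n_correct / nrow(dataset$features))
}

#' Built-in classifiers for evaluation and tuning
#'
#' \code{make_knn_classifier} wraps the package's deterministic KNN;
#' \code{make_mlp_classifier} wraps a single-hidden-layer perceptron
#' (\code{nnet::nnet}) as the desk-scale tunable classifier. Both standardize
#' features with statistics fitted on the training split only.
#'
#' @param k Neighbourhood size for the KNN classifier.
#' @param hidden_width Hidden-layer size of the MLP.
#' @param decay Weight-decay (L2 regularization) strength of the MLP.
#' @param maxit Maximum training iterations of the MLP.
#' @param fit_seed Seed applied locally to the MLP weight initialization so
#'   that fitting is reproducible without disturbing the caller's random
#'   stream.
#' @return A classifier object: \code{list(fit, predict, spec)}.
#' @export
make_knn_classifier <- function(k = 5L) {
  list(
    spec = list(type = "knn", k = k),
    fit = function(train) train,
    predict = function(model, eval) knn_predict(model, eval, NULL, k)
  )
}

#' @rdname make_knn_classifier
#' @export
make_mlp_classifier <- function(hidden_width = 4L, decay = 1e-3, maxit = 100L,
                                fit_seed = 1L) {
  list(
    spec = list(type = "mlp", hidden_width = hidden_width, decay = decay,
                maxit = maxit),
    fit = function(train) {
      mu <- colMeans(train$features)
      sdv <- apply(train$features, 2L, stats::sd)
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      x <- sweep(sweep(train$features, 2L, mu), 2L, sdv, "/")
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(fit_seed)
      fit <- nnet::nnet(x, nnet::class.ind(train$labels),
                        size = hidden_width, decay = decay, maxit = maxit,
                        softmax = TRUE, trace = FALSE)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      list(fit = fit, mu = mu, sdv = sdv, levels = levels(train$labels))
    },
    predict = function(model, eval) {
      x <- sweep(sweep(eval$features, 2L, model$mu), 2L, model$sdv, "/")
      p <- stats::predict(model$fit, x)
      factor(model$levels[max.col(p, ties.method = "first")],
             levels = model$levels)
    }
  )
}
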