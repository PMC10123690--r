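#' Read a feature table from CSV
#'
#' Expects a header row, one designated label column, and numeric feature
#' columns. Coercion failures are explicit errors (a textual \code{"NA"} or
#' any non-numeric cell in a feature column aborts the load rather than
#' becoming a silent missing value). Row order is preserved.
#'
#' @param path CSV file path.
#' @param label_col Name of the label column.
#' @return A \code{\link{feature_dataset}}.
#' @export
load_feature_csv <- function(path, label_col) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE, na.strings = character(0))
  if (!(label_col %in% names(raw)))
    stop("label column '", label_col, "' not found in ", path, call. = FALSE)
  feat_names <- names(raw)[names(raw) != label_col]
  if (anyDuplicated(feat_names))
    stop("duplicate feature names in ", path, ": ",
         paste(unique(feat_names[duplicated(feat_names)]), collapse = ", "),
         call. = FALSE)
  if (length(feat_names) < 1L)
    stop("no feature columns besides the label column", call. = FALSE)
  X <- matrix(NA_real_, nrow(raw), length(feat_names),
              dimnames = list(NULL, feat_names))
  for (nm in feat_names) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop("non-numeric cell in feature column '", nm, "' (row ", bad[1L],
           ": \"", raw[[nm]][bad[1L]], "\")", call. = FALSE)
    X[, nm] <- v
  }
  feature_dataset(X, raw[[label_col]])
}

#' Write a feature table to CSV
#'
#' @param dataset A \code{\link{feature_dataset}}.
#' @param path Output path.
#' @param label_col Name used for the label column (default \code{"class"}).
#' @return The path, invisibly.
#' @export
write_feature_csv <- function(dataset, path, label_col = "class") {
  stopifnot(inherits(dataset, "feature_dataset"))
  df <- as.data.frame(dataset$features)
  df[[label_col]] <- as.character(dataset$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export / import a feature mask as JSON
#'
#' @param mask A \code{\link{feature_mask}}.
#' @param feature_names Character vector, one name per bit.
#' @param path JSON file path.
#' @return \code{write_mask_json} returns the path invisibly;
#'   \code{read_mask_json} returns a list with \code{mask} and
#'   \code{feature_names}.
#' @export
write_mask_json <- function(mask, feature_names, path) {
  stopifnot(inherits(mask, "feature_mask"),
            length(feature_names) == length(mask$bits))
  jsonlite::write_json(
    list(schema_version = 1L, feature_names = feature_names,
         bits = mask$bits, selected_count = mask$selected_count,
         selected_fraction = mask$selected_fraction),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_json
#' @export
read_mask_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(mask = feature_mask(obj$bits), feature_names = obj$feature_names)
}

#' Tabular report of a feature-selection experiment
#'
#' Builds the standard evaluation layout from per-method run results: one
#' table of aggregate run statistics (average error, average select size,
#' average/best/worst/std fitness), one of descriptive statistics of the
#' per-run errors, plus the one-way ANOVA over methods and the per-method
#' one-sample Wilcoxon signed-rank tests against theoretical median 0.
#'
#' @param experiment Named per-method list of run-result lists, as returned
#'   by \code{\link{run_fs_experiment}}.
#' @return A list of class \code{fs_report}: \code{summary} (data frame,
#'   metrics x methods), \code{descriptives} (data frame), \code{anova}
#'   (an \code{anova_result}), \code{wilcoxon} (named list of
#'   \code{wilcoxon_result}).
#' @export
report_fs_experiment <- function(experiment) {
  stopifnot(length(experiment) >= 1L)
  stats_by_m <- lapply(experiment, fs_run_statistics)
  summary_df <- data.frame(row.names = c(
    "Average error", "Average select size", "Average fitness",
    "Best fitness", "Worst fitness", "Std fitness"))
  for (m in names(experiment)) {
    s <- stats_by_m[[m]]
    summary_df[[m]] <- c(s$average_error, s$average_select_size,
                         s$mean_fitness, s$best_fitness, s$worst_fitness,
                         s$std_fitness)
  }
  errors_by_m <- lapply(experiment, function(runs)
    vapply(runs, function(r) r$error_rate, numeric(1L)))
  desc_df <- data.frame(row.names = c(
    "Number of values", "Minimum", "25% Percentile", "Median",
    "75% Percentile", "Maximum", "Range", "Mean", "Std. deviation",
    "Std. error of mean"))
  for (m in names(experiment)) {
    d <- descriptive_stats(errors_by_m[[m]])
    desc_df[[m]] <- c(d$n, d$min, d$q25, d$median, d$q75, d$max, d$range,
                      d$mean, d$sd, d$sem)
  }
  anova <- if (length(experiment) >= 2L &&
               all(lengths(errors_by_m) >= 2L)) anova_oneway(errors_by_m) else NULL
  wilcoxon <- lapply(errors_by_m, wilcoxon_signed_rank, theoretical_median = 0)
  structure(list(summary = summary_df, descriptives = desc_df,
                 anova = anova, wilcoxon = wilcoxon),
            class = "fs_report")
}

#' Write an experiment report to disk
#'
#' Emits the summary and descriptive tables as CSV and the full report
#' (including ANOVA and Wilcoxon results) as JSON.
#'
#' @param report An \code{fs_report} from \code{\link{report_fs_experiment}}.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_fs_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "summary.csv")
  p2 <- file.path(dir, "descriptives.csv")
  p3 <- file.path(dir, "report.json")
  utils::write.csv(report$summary, p1)
  utils::write.csv(report$descriptives, p2)
  jsonlite::write_json(list(
    schema_version = 1L,
    summary = cbind(metric = rownames(report$summary), report$summary),
    descriptives = cbind(metric = rownames(report$descriptives),
                         report$descriptives),
    anova = if (!is.null(report$anova)) unclass(report$anova),
    wilcoxon = lapply(report$wilcoxon, unclass)
  ), p3, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(p1, p2, p3))
}

#' Run the staged synthetic end-to-end pipeline
#'
#' Executes the full desk-scale workflow on synthetic data: (1) generate a
#' synthetic feature table and write it as CSV; (2) select features with the
#' binary DDTPSO wrapper and export the mask; (3) tune the built-in MLP
#' classifier on the selected features; (4) evaluate and write report
#' tables. Every stage is seeded from \code{seed_base} plus a fixed stage
#' offset and leaves a JSON/CSV artifact in \code{out_dir}; a stage failure
#' halts the pipeline with the stage name while earlier artifacts persist.
#'
#' @param config Optional named list overriding pieces of the default
#'   configuration: \code{synth} (a \code{\link{synthetic_spec}}), \code{fs}
#'   (an \code{\link{fs_config}}), \code{tuning} (an
#'   \code{\link{optimizer_config}} for the tuner), \code{n_runs}.
#' @param out_dir Output directory.
#' @param seed_base Integer base seed.
#' @return A list of class \code{pipeline_result} with the per-stage results
#'   and artifact paths.
#' @export
run_pipeline <- function(config = list(), out_dir, seed_base = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  synth_spec <- config$synth %||% synthetic_spec(seed = seed_base)
  fs_cfg <- config$fs %||% fs_config()
  tune_cfg <- config$tuning %||%
    optimizer_config(n_agents = 5L, n_iterations = 10L, bounds = c(0, 1))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  gen <- stage("synth", {
    g <- gen_feature_dataset(synth_spec)
    write_feature_csv(g$dataset, file.path(out_dir, "features.csv"))
    g
  })
  fs_res <- stage("select", {
    fs_cfg$optimizer$seed <- as.integer(seed_base + 100L)
    r <- select_features(gen$dataset, fs_cfg)
    write_mask_json(r$best_mask, gen$dataset$feature_names,
                    file.path(out_dir, "fsresult.json"))
    r
  })
  tuned <- stage("tune", {
    tune_cfg$seed <- as.integer(seed_base + 200L)
    tr <- tune_classifier(gen$dataset, fs_res$best_mask,
                          optimizer_config = tune_cfg)
    jsonlite::write_json(list(
      schema_version = 1L, best_hyperparams = tr$best_hyperparams,
      validation_error = tr$validation_error,
      test_accuracy = tr$test_accuracy,
      test_metrics = unclass(tr$test_metrics)),
      file.path(out_dir, "tuned.json"), auto_unbox = TRUE, digits = NA)
    tr
  })
  report <- stage("evaluate", {
    ev <- kfold_evaluate(gen$dataset, fs_res$best_mask,
                         make_knn_classifier(fs_cfg$knn_k), k = 10L,
                         seed = seed_base + 300L)
    df <- data.frame(metric = names(unclass(ev$metrics)),
                     value = unlist(unclass(ev$metrics), use.names = FALSE))
    utils::write.csv(df, file.path(out_dir, "report.csv"), row.names = FALSE)
    ev
  })
  summary <- list(
    schema_version = 1L, seed_base = as.integer(seed_base),
    n_features = ncol(gen$dataset$features),
    n_selected = fs_res$best_mask$selected_count,
    fs_fitness = fs_res$best_fitness,
    fs_validation_error = fs_res$error_rate,
    tuned_validation_error = tuned$validation_error,
    tuned_test_accuracy = tuned$test_accuracy,
    kfold_accuracy = report$accuracy)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(synth = gen, fs = fs_res, tuned = tuned, evaluation = report,
                 summary = summary, out_dir = out_dir),
            class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
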