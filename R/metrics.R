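#' One-vs-rest confusion counts
#'
#' Reduces a (possibly multiclass) prediction to binary counts against a
#' designated positive label.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive_label The label treated as positive; it must occur in at
#'   least one of the two vectors.
#' @return An object of class \code{confusion_counts} with integer fields
#'   \code{TP}, \code{TN}, \code{FP}, \code{FN}.
#' @export
confusion_counts <- function(y_true, y_pred, positive_label) {
  if (length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' must have equal length", call. = FALSE)
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (!(positive_label %in% c(y_true, y_pred)))
    stop("label '", positive_label, "' absent from both label vectors",
         call. = FALSE)
  tp <- sum(y_true == positive_label & y_pred == positive_label)
  tn <- sum(y_true != positive_label & y_pred != positive_label)
  fp <- sum(y_true != positive_label & y_pred == positive_label)
  fn <- sum(y_true == positive_label & y_pred != positive_label)
  confusion_counts_object(tp, tn, fp, fn)
}

confusion_counts_object <- function(TP, TN, FP, FN) {
  structure(list(TP = as.numeric(TP), TN = as.numeric(TN),
                 FP = as.numeric(FP), FN = as.numeric(FN)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes the six standard derived metrics: accuracy
#' \eqn{(TP+TN)/(TP+TN+FP+FN)}, sensitivity \eqn{TP/(TP+FN)}, specificity
#' \eqn{TN/(TN+FP)}, positive predictive value \eqn{TP/(TP+FP)}, negative
#' predictive value \eqn{TN/(TN+FN)}, and the F score
#' \eqn{TP/(TP+0.5(FP+FN))}. A metric whose denominator is zero is reported
#' as \code{NA} (missing), never as 0. Count fields may be equal-length
#' vectors, in which case all metrics are computed element-wise.
#'
#' @param counts A \code{\link{confusion_counts}} object, or any list with
#'   numeric fields \code{TP}, \code{TN}, \code{FP}, \code{FN}.
#' @return For scalar counts, a \code{metrics_report} (named list); for
#'   vector counts, a data frame with one row per confusion table.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (any(total <= 0))
    stop("confusion counts must total at least one sample", call. = FALSE)
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- list(
    accuracy = (TP + TN) / total,
    sensitivity = safe_div(TP, TP + FN),
    specificity = safe_div(TN, TN + FP),
    precision_ppv = safe_div(TP, TP + FP),
    npv = safe_div(TN, TN + FN),
    f_score = safe_div(TP, TP + 0.5 * (FP + FN))
  )
  if (length(TP) == 1L) return(structure(out, class = "metrics_report"))
  as.data.frame(out)
}

#' @export
print.metrics_report <- function(x, ...) {
  for (nm in names(x))
    cat(format(nm, width = 14), format(round(x[[nm]], 4)), "\n")
  invisible(x)
}

#' Aggregate statistics over repeated feature-selection runs
#'
#' Summarizes M independent runs: mean/best/worst/standard deviation of the
#' per-run best fitness, the mean per-run validation error, and the mean
#' selected-subset size expressed as a fraction of the full feature count.
#' The standard deviation uses the M - 1 denominator and is \code{NA} for a
#' single run.
#'
#' @param results List of run results as returned by
#'   \code{\link{select_features}} (each with \code{best_fitness},
#'   \code{error_rate} and \code{best_mask}).
#' @return An object of class \code{run_statistics}.
#' @export
fs_run_statistics <- function(results) {
  stopifnot(length(results) >= 1L)
  fit <- vapply(results, function(r) r$best_fitness, numeric(1L))
  err <- vapply(results, function(r) r$error_rate, numeric(1L))
  frac <- vapply(results, function(r) r$best_mask$selected_fraction, numeric(1L))
  structure(list(
    mean_fitness = mean(fit),
    best_fitness = min(fit),
    worst_fitness = max(fit),
    std_fitness = if (length(fit) >= 2L) stats::sd(fit) else NA_real_,
    average_error = mean(err),
    average_select_size = mean(frac),
    n_runs = length(results)
  ), class = "run_statistics")
}

#' Descriptive statistics of a numeric vector
#'
#' Minimum, maximum, median, quartiles (linear interpolation between order
#' statistics), range, mean, standard deviation (n - 1), standard error of
#' the mean, and the count.
#'
#' @param values Numeric vector, length at least 1.
#' @return A named list of class \code{descriptive_stats}.
#' @export
descriptive_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("'values' must be non-empty", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  s <- if (length(values) >= 2L) stats::sd(values) else NA_real_
  structure(list(
    n = length(values), min = min(values), max = max(values),
    q25 = q[1L], median = q[2L], q75 = q[3L],
    range = max(values) - min(values),
    mean = mean(values), sd = s,
    sem = if (is.na(s)) NA_real_ else s / sqrt(length(values))
  ), class = "descriptive_stats")
}

#' One-way analysis of variance
#'
#' Textbook between/within decomposition fitted through \code{stats::lm}; the
#' F statistic is the treatment mean square over the residual mean square,
#' with the p value from the F distribution. Zero residual variance is
#' reported as an infinite F with p = 0 and \code{degenerate = TRUE}.
#'
#' @param groups List of numeric vectors (at least 2 groups, each with at
#'   least 2 values).
#' @return An object of class \code{anova_result} with fields
#'   \code{ss_treatment}, \code{ss_residual}, \code{ss_total},
#'   \code{df_treatment}, \code{df_residual}, \code{df_total},
#'   \code{ms_treatment}, \code{ms_residual}, \code{f_stat}, \code{p_value},
#'   \code{degenerate}.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1L)) < 2L))
    stop("each group needs at least 2 values", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1L))))
  # a perfect fit triggers lm's reliability warning; degeneracy is flagged below
  tab <- suppressWarnings(stats::anova(stats::lm(y ~ g)))
  ss_t <- tab$`Sum Sq`[1L]; ss_r <- tab$`Sum Sq`[2L]
  df_t <- tab$Df[1L]; df_r <- tab$Df[2L]
  ms_t <- ss_t / df_t; ms_r <- ss_r / df_r
  degenerate <- ms_r <= .Machine$double.eps * max(1, ms_t)
  f <- if (degenerate) Inf else ms_t / ms_r
  p <- if (degenerate) 0 else stats::pf(f, df_t, df_r, lower.tail = FALSE)
  structure(list(ss_treatment = ss_t, ss_residual = ss_r,
                 ss_total = ss_t + ss_r,
                 df_treatment = df_t, df_residual = df_r,
                 df_total = df_t + df_r,
                 ms_treatment = ms_t, ms_residual = ms_r,
                 f_stat = f, p_value = p, degenerate = degenerate),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  p_txt <- if (x$p_value < 1e-4) "p < 0.0001" else
    sprintf("p = %.4f", x$p_value)
  cat(sprintf("One-way ANOVA: F (%d, %d) = %.4g, %s\n",
              x$df_treatment, x$df_residual, x$f_stat, p_txt))
  cat(sprintf("  SS treatment %.6g, SS residual %.6g, SS total %.6g\n",
              x$ss_treatment, x$ss_residual, x$ss_total))
  invisible(x)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests the values against a hypothesized (theoretical) median. Zero
#' differences are dropped; absolute differences are ranked with midranks
#' under ties. The statistic reported is the sum of signed ranks
#' \eqn{W = W^+ - W^-}. The two-sided p value is exact (enumeration over the
#' \eqn{2^n} sign assignments via the signed-rank null distribution) for
#' \eqn{n \le 25} with untied ranks, and a normal approximation with tie
#' correction and continuity correction otherwise.
#'
#' @param values Numeric vector.
#' @param theoretical_median Null median (default 0).
#' @return An object of class \code{wilcoxon_result}: \code{w_stat},
#'   \code{sum_positive_ranks}, \code{sum_negative_ranks},
#'   \code{p_two_tailed}, \code{n} (values remaining after dropping zero
#'   differences), \code{exact}.
#' @export
wilcoxon_signed_rank <- function(values, theoretical_median = 0) {
  d <- as.numeric(values) - theoretical_median
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("all differences from the theoretical median are zero", call. = FALSE)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  ties <- any(duplicated(r))
  if (n <= 25L && !ties) {
    exact <- TRUE
    # P(W+ <= w) and P(W+ >= w) under the exact signed-rank null
    p_low <- stats::psignrank(w_pos, n)
    p_high <- stats::psignrank(w_pos - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_low, p_high))
  } else {
    exact <- FALSE
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  }
  structure(list(w_stat = w_pos - w_neg,
                 sum_positive_ranks = w_pos, sum_negative_ranks = w_neg,
                 p_two_tailed = p, n = n, exact = exact),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g (W+ = %g, W- = %g), n = %d\n",
              x$w_stat, x$sum_positive_ranks, x$sum_negative_ranks, x$n))
  cat(sprintf("  two-tailed p = %.4g (%s)\n", x$p_two_tailed,
              if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}

#' Simple linear regression report
#'
#' Ordinary least squares of \code{y} on \code{x} with standard errors, 95%
#' confidence intervals (t distribution, n - 2 df), the coefficient of
#' determination, and the F test for a non-zero slope.
#'
#' @param x,y Equal-length numeric vectors, n >= 3; \code{x} must not be
#'   constant.
#' @return An object of class \code{regression_report}: \code{slope},
#'   \code{intercept}, \code{se_slope}, \code{se_intercept},
#'   \code{ci95_slope}, \code{ci95_intercept}, \code{r_square},
#'   \code{f_stat}, \code{p_value}, \code{n}.
#' @export
regression_report <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("'x' is constant; slope undefined", call. = FALSE)
  constant_y <- stats::sd(y) == 0   # nothing to explain: R^2 and F are 0
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits warn; handled via guards
  co <- sm$coefficients
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  fs <- sm$fstatistic
  p <- if (constant_y || is.null(fs) || !is.finite(fs[1L])) NA_real_ else
    stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE)
  r2 <- if (constant_y || !is.finite(sm$r.squared)) 0 else sm$r.squared
  structure(list(
    slope = unname(co["x", "Estimate"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    se_slope = unname(co["x", "Std. Error"]),
    se_intercept = unname(co["(Intercept)", "Std. Error"]),
    ci95_slope = unname(ci["x", ]),
    ci95_intercept = unname(ci["(Intercept)", ]),
    r_square = r2,
    f_stat = if (is.null(fs) || !is.finite(fs[1L])) 0 else unname(fs[1L]),
    p_value = unname(p),
    n = length(x)
  ), class = "regression_report")
}
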