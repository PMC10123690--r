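test_that("confusion counts enumerate the four outcomes", {
  cc <- confusion_counts(c("+", "+", "-", "-"), c("+", "-", "+", "-"), "+")
  expect_equal(unlist(cc[c("TP", "FN", "FP", "TN")]),
               c(TP = 1, FN = 1, FP = 1, TN = 1))
  perfect <- confusion_counts(c("+", "-", "+"), c("+", "-", "+"), "+")
  expect_equal(perfect$FP + perfect$FN, 0)
  # swapping the positive label swaps (TP, FN) with (TN, FP)
  sw <- confusion_counts(c("+", "+", "-", "-"), c("+", "-", "-", "-"), "+")
  sw2 <- confusion_counts(c("+", "+", "-", "-"), c("+", "-", "-", "-"), "-")
  expect_equal(c(sw$TP, sw$FN), c(sw2$TN, sw2$FP))
  expect_error(confusion_counts(c("a", "b"), c("a", "b"), "z"), "absent")
  expect_error(confusion_counts(c("a", "b"), c("a"), "a"), "length")
})

test_that("classification metrics follow the six standard formulas", {
  m <- classification_metrics(ddtpso:::confusion_counts_object(3, 90, 2, 5))
  expect_equal(m$accuracy, 0.93)
  expect_equal(m$sensitivity, 0.375)
  expect_equal(m$specificity, 90 / 92)
  expect_equal(m$precision_ppv, 0.6)
  expect_equal(m$npv, 90 / 95)
  expect_equal(m$f_score, 3 / (3 + 0.5 * 7))
  all1 <- classification_metrics(ddtpso:::confusion_counts_object(5, 5, 0, 0))
  expect_true(all(unlist(all1) == 1))
  # zero denominators are missing, never zero
  deg <- classification_metrics(ddtpso:::confusion_counts_object(0, 10, 0, 0))
  expect_true(is.na(deg$sensitivity))
  expect_true(is.na(deg$precision_ppv))
  expect_true(is.na(deg$f_score))
  expect_equal(deg$accuracy, 1)
})

test_that("run statistics aggregate fitness, error and subset size", {
  fake <- function(fit, err, bits) list(best_fitness = fit, error_rate = err,
                                        best_mask = feature_mask(bits))
  runs <- list(fake(0.5, 0.1, c(1, 0, 0, 0)), fake(0.6, 0.2, c(1, 1, 0, 0)),
               fake(0.7, 0.3, c(1, 1, 1, 0)))
  s <- fs_run_statistics(runs)
  expect_equal(s$mean_fitness, 0.6)
  expect_equal(s$best_fitness, 0.5)
  expect_equal(s$worst_fitness, 0.7)
  expect_equal(s$std_fitness, 0.1)          # M - 1 denominator
  expect_equal(s$average_error, 0.2)
  expect_equal(s$average_select_size, 0.5)  # fraction of d = 4
  one <- fs_run_statistics(runs[1])
  expect_true(is.na(one$std_fitness))
  # ordering invariant on random inputs
  set.seed(4)
  for (i in 1:10) {
    rr <- lapply(runif(5), function(f) fake(f, runif(1), c(1, 0)))
    st <- fs_run_statistics(rr)
    expect_lte(st$best_fitness, st$mean_fitness)
    expect_lte(st$mean_fitness, st$worst_fitness)
  }
})

test_that("descriptive statistics use linear-interpolation quartiles", {
  d <- descriptive_stats(1:11)
  expect_equal(d$median, 6)
  expect_equal(d$q25, 3.5)
  expect_equal(d$q75, 8.5)
  expect_equal(d$range, 10)
  expect_equal(d$sem, sd(1:11) / sqrt(11))
  cst <- descriptive_stats(rep(2, 5))
  expect_equal(cst$range, 0)
  expect_equal(cst$sd, 0)
  set.seed(9)
  for (i in 1:10) {
    d <- descriptive_stats(rnorm(sample(2:40, 1)))
    expect_true(d$min <= d$q25 && d$q25 <= d$median &&
                  d$median <= d$q75 && d$q75 <= d$max)
  }
})

test_that("one-way ANOVA reproduces the textbook decomposition", {
  set.seed(11)
  groups <- replicate(4, rnorm(7, mean = runif(1)), simplify = FALSE)
  a <- anova_oneway(groups)
  y <- unlist(groups)
  expect_equal(a$ss_total, sum((y - mean(y))^2))  # brute-force total SS
  expect_equal(a$ss_treatment + a$ss_residual, a$ss_total)
  expect_equal(a$df_treatment + a$df_residual, a$df_total)
  expect_equal(a$df_total, length(y) - 1L)
  # against the base-R reference
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ref <- stats::oneway.test(y ~ g, var.equal = TRUE)
  expect_equal(a$f_stat, unname(ref$statistic))
  expect_equal(a$p_value, unname(ref$p.value))
  # identical groups shifted nowhere: zero treatment SS
  same <- replicate(3, c(1, 2, 3), simplify = FALSE)
  expect_equal(anova_oneway(same)$ss_treatment, 0)
  # degenerate: no residual variation
  deg <- anova_oneway(list(c(1, 1), c(2, 2)))
  expect_true(deg$degenerate)
  expect_equal(deg$f_stat, Inf)
  expect_equal(deg$p_value, 0)
  expect_error(anova_oneway(list(1:3)), "2 groups")
})

test_that("Wilcoxon signed-rank statistics and exact p values are correct", {
  w <- wilcoxon_signed_rank(runif(11, 0.1, 1), 0)
  expect_equal(w$sum_positive_ranks, 66)
  expect_equal(w$sum_negative_ranks, 0)
  expect_equal(w$w_stat, 66)
  w10 <- wilcoxon_signed_rank(seq(0.5, 0.95, length.out = 10), 0)
  expect_equal(w10$w_stat, 55)
  expect_true(w10$exact)
  expect_equal(w10$p_two_tailed, 2 / 2^10)
  # sign symmetry: signed-rank sum 0
  sym <- wilcoxon_signed_rank(c(-2, -1, 1, 2), 0)
  expect_equal(sym$w_stat, 0)
  # agreement with the base-R reference on random tie-free data
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(12)
    ref <- suppressWarnings(stats::wilcox.test(x, mu = 0, exact = TRUE))
    mine <- wilcoxon_signed_rank(x, 0)
    expect_equal(mine$sum_positive_ranks, unname(ref$statistic))
    expect_equal(mine$p_two_tailed, ref$p.value)
  }
  # tied data fall back to the corrected normal approximation
  tied <- wilcoxon_signed_rank(c(1, 1, 2, 2, 3, 3, -1, -2, 4, 4, 5, 5), 0)
  expect_false(tied$exact)
  ref <- suppressWarnings(stats::wilcox.test(
    c(1, 1, 2, 2, 3, 3, -1, -2, 4, 4, 5, 5), mu = 0, exact = FALSE,
    correct = TRUE))
  expect_equal(tied$p_two_tailed, ref$p.value)
  expect_error(wilcoxon_signed_rank(c(0, 0), 0), "zero")
})

test_that("regression report matches the closed-form normal equations", {
  x <- c(0, 1, 2, 3, 4)
  r <- regression_report(x, 2 * x + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_square, 1)
  flat <- regression_report(x, rep(3, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_square, 0)
  set.seed(17)
  x <- rnorm(10); y <- 1.5 * x + rnorm(10)
  r <- regression_report(x, y)
  # normal-equation oracle
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  res <- y - b0 - b1 * x
  s2 <- sum(res^2) / (10 - 2)
  se1 <- sqrt(s2 / sum((x - mean(x))^2))
  expect_equal(r$slope, b1)
  expect_equal(r$intercept, b0)
  expect_equal(r$se_slope, se1)
  expect_equal(r$ci95_slope,
               b1 + c(-1, 1) * qt(0.975, 8) * se1)
  expect_true(r$ci95_intercept[1] <= b0 && b0 <= r$ci95_intercept[2])
  expect_error(regression_report(rep(1, 5), rnorm(5)), "constant")
})

test_that("experiment reports assemble the summary and test tables", {
  fake_run <- function(fit, err) list(best_fitness = fit, error_rate = err,
                                      best_mask = feature_mask(c(1, 0, 1, 0)))
  ex <- list(
    m1 = lapply(seq(0.50, 0.60, length.out = 5), function(f) fake_run(f, f - 0.4)),
    m2 = lapply(seq(0.55, 0.70, length.out = 5), function(f) fake_run(f, f - 0.4)))
  rpt <- report_fs_experiment(ex)
  expect_equal(colnames(rpt$summary), c("m1", "m2"))
  expect_equal(rpt$summary["Average fitness", "m1"], mean(seq(0.50, 0.60, length.out = 5)))
  expect_equal(rpt$descriptives["Number of values", "m2"], 5)
  expect_s3_class(rpt$anova, "anova_result")
  expect_equal(rpt$anova$df_treatment, 1L)
  expect_equal(rpt$anova$df_residual, 8L)
  expect_equal(rpt$wilcoxon$m1$sum_positive_ranks, 15)  # 5 positive values
  td <- withr::local_tempdir()
  paths <- write_fs_report(rpt, td)
  expect_true(all(file.exists(file.path(td, c("summary.csv", "descriptives.csv",
                                              "report.json")))))
})
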