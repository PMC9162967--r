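test_that("normality routing picks the right test and summaries", {
  set.seed(406)
  # identical normal-looking samples: t-test route, p = 1
  g <- rnorm(20, 70, 5)
  cmp <- route_and_compare(list(g, g), "continuous", "duration")
  expect_equal(cmp$test, "t_test")
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$summaries[[1]]$kind, "mean_sd")
  # a heavily skewed group forces the Mann-Whitney route
  sk <- exp(rnorm(30, 0, 1.5))
  cmp2 <- route_and_compare(list(sk, rnorm(30, 2, 1)), "continuous", "x")
  expect_equal(cmp2$test, "mann_whitney")
  expect_equal(cmp2$summaries[[1]]$kind, "median_iqr")
  expect_error(route_and_compare(list(1:2, 1:10), "continuous", "tiny"),
               "tiny")
})

test_that("categorical routing switches between Fisher and chi-square", {
  # balanced 2x2 with no association: p = 1 whichever route is taken
  # (expected cells are exactly 5, the strict < 5 rule keeps chi-square)
  cmp <- route_and_compare(matrix(c(5, 5, 5, 5), 2), "categorical", "arm")
  expect_equal(cmp$p_value, 1)
  # an expected cell below 5 routes to Fisher
  cmp_f <- route_and_compare(matrix(c(4, 5, 5, 5), 2), "categorical", "arm")
  expect_equal(cmp_f$test, "fisher")
  # all expected counts >= 5 -> Pearson chi-square
  big <- matrix(c(30, 20, 22, 28), 2)
  cmp2 <- route_and_compare(big, "categorical", "arm")
  expect_equal(cmp2$test, "chi_square")
  expect_gt(cmp2$p_value, 0)
  # factor-list input builds the table itself
  cmp3 <- route_and_compare(list(rep(c("m", "f"), c(27, 3)),
                                 rep(c("m", "f"), c(11, 0))),
                            "categorical", "gender")
  expect_equal(cmp3$test, "fisher")
})

test_that("a one-sd shift is detected reliably by the routed test", {
  set.seed(407)
  hits <- vapply(1:500, function(i) {
    a <- rnorm(30); b <- rnorm(30, 1)
    route_and_compare(list(a, b), "continuous")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("Spearman correlation handles the exact and error cases", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 1:2), "3 complete pairs")
})

test_that("duration-grafts rank link is recovered from a synthetic cohort", {
  spec <- cohort_spec(seed = 33)
  cohort <- generate_cohort(spec)
  dur <- vapply(cohort, function(r) r$covariates$duration_min, numeric(1))
  gr <- vapply(cohort, function(r) as.numeric(r$covariates$n_grafts),
               numeric(1))
  est <- spearman_cor(dur, gr)$rho
  expect_lt(abs(est - 0.33), 0.25)
})

test_that("ROC analysis is exact on separated and tied inputs", {
  # perfectly separated predictor
  s <- roc_analysis(c(1, 2, 3, 11, 12, 13),
                    c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(s$auroc, 1)
  expect_equal(s$sensitivity, 1)
  expect_equal(s$specificity, 1)
  expect_gt(s$optimal_cutoff, 3)
  expect_lt(s$optimal_cutoff, 11)
  # all ties: AUROC 1/2 by the pair-count convention, flagged degenerate
  d <- roc_analysis(rep(1, 6), c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(d$auroc, 0.5)
  expect_true(d$degenerate)
  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "both outcome classes")
})

test_that("AUROC equals the exhaustive pair count, with invariances", {
  set.seed(408)
  for (i in 1:60) {
    n <- sample(6:50, 1)
    x <- if (i %% 2) rnorm(n) else sample(0:6, n, replace = TRUE)  # ties
    y <- rep(FALSE, n)
    y[sample(n, sample(2:(n - 2), 1))] <- TRUE
    a <- roc_analysis(x, y)$auroc
    expect_identical(a, pair_auroc(x, y))
    # label-flip antisymmetry
    expect_equal(a + roc_analysis(x, !y)$auroc, 1, tolerance = 1e-12)
    # strictly increasing transform leaves the AUROC unchanged
    expect_equal(roc_analysis(exp(x / 3), y)$auroc, a, tolerance = 1e-12)
  }
})

test_that("ROC output agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(409)
  x <- c(rnorm(25, 1), rnorm(15, 2))
  y <- rep(c(FALSE, TRUE), c(25, 15))
  ours <- roc_analysis(x, y)
  ref <- pROC::roc(response = y, predictor = x, direction = "<",
                   quiet = TRUE)
  expect_equal(ours$auroc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  co <- pROC::coords(ref, "best", best.method = "youden",
                     ret = c("sensitivity", "specificity"))
  expect_equal(ours$sensitivity, co$sensitivity, tolerance = 1e-12)
  expect_equal(ours$specificity, co$specificity, tolerance = 1e-12)
})

test_that("permuted labels give a null AUROC centred on one half", {
  set.seed(410)
  x <- rnorm(40)
  y <- rep(c(TRUE, FALSE), c(12, 28))
  aucs <- vapply(1:1000, function(i) roc_analysis(x, sample(y))$auroc,
                 numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("the Hanley-McNeil interval and p-value behave sensibly", {
  set.seed(411)
  x <- c(rnorm(30), rnorm(12, 1.5))
  y <- rep(c(FALSE, TRUE), c(30, 12))
  s <- roc_analysis(x, y)
  expect_true(s$ci_low <= s$auroc && s$auroc <= s$ci_high)
  expect_true(s$ci_low >= 0 && s$ci_high <= 1)
  expect_lt(s$p_value, 0.05)
  # a hopeless predictor keeps a CI straddling 1/2
  s0 <- roc_analysis(rnorm(42), rep(c(FALSE, TRUE), 21))
  expect_gt(s0$p_value, 0.001)
})

test_that("roc_table reports every predictor and flags degenerate ones", {
  set.seed(412)
  panel <- data.frame(patient_id = sprintf("P%02d", 1:30),
                      good = c(rnorm(20), rnorm(10, 2)),
                      flat = rep(7, 30),
                      noise = rnorm(30))
  labels <- data.frame(patient_id = panel$patient_id,
                       impaired = rep(c(FALSE, TRUE), c(20, 10)))
  tab <- roc_table(panel, labels)
  expect_equal(nrow(tab), 3L)
  expect_true(tab$degenerate[tab$predictor == "flat"])
  expect_equal(tab$auroc[tab$predictor == "flat"], 0.5)
  expect_gt(tab$auroc[tab$predictor == "good"], 0.7)
  expect_error(roc_table(panel, rep(FALSE, 30)), "2 patients per")
})
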