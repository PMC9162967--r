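# Group comparisons with normality routing, Spearman correlation, and ROC
# analysis of burden predictors.

#' Compare a variable between two groups with normality routing
#'
#' Continuous variables: the Shapiro-Wilk test is applied to each group at
#' alpha = 0.05; when both groups pass, groups are summarised as mean (SD)
#' and compared by the independent Student t test, otherwise as
#' median \[IQR\] and compared by the Mann-Whitney U test. Categorical
#' variables (given as a 2-way contingency table or two factors) are
#' compared by Fisher's exact test when any expected cell count is below 5
#' and by the Pearson chi-square test otherwise.
#'
#' @param values_by_group for continuous variables, a list of two numeric
#'   vectors (each n >= 3); for categorical, either a contingency
#'   `table`/matrix or a list of two factors/character vectors.
#' @param variable_kind `"continuous"` or `"categorical"`.
#' @param variable name used in error messages and reports.
#' @param alpha_normality per-group Shapiro-Wilk significance level.
#' @return a `group_comparison`: summaries per group, the test used, and
#'   the p value.
#' @export
route_and_compare <- function(values_by_group,
                              variable_kind = c("continuous", "categorical"),
                              variable = "variable",
                              alpha_normality = 0.05) {
  variable_kind <- match.arg(variable_kind)
  if (variable_kind == "continuous") {
    stopifnot(is.list(values_by_group), length(values_by_group) == 2L)
    g <- lapply(values_by_group, function(v) as.numeric(v[!is.na(v)]))
    if (any(lengths(g) < 3L))
      stop("variable '", variable,
           "': each group needs at least 3 observations", call. = FALSE)
    normal <- vapply(g, function(v) {
      if (length(unique(v)) == 1L) return(FALSE)  # degenerate: route nonparametric
      shapiro.test(v)$p.value > alpha_normality
    }, logical(1))
    if (all(normal)) {
      tt <- t.test(g[[1]], g[[2]], var.equal = TRUE)
      summaries <- lapply(g, function(v)
        list(kind = "mean_sd", mean = mean(v), sd = sd(v),
             label = sprintf("%.1f (%.1f)", mean(v), sd(v))))
      test <- "t_test"; p <- tt$p.value
    } else {
      wt <- suppressWarnings(wilcox.test(g[[1]], g[[2]]))
      summaries <- lapply(g, function(v) {
        q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
        list(kind = "median_iqr", median = q[2], q1 = q[1], q3 = q[3],
             label = sprintf("%.1f [%.1f-%.1f]", q[2], q[1], q[3]))
      })
      test <- "mann_whitney"; p <- wt$p.value
    }
  } else {
    tab <- if (is.table(values_by_group) || is.matrix(values_by_group))
      as.table(as.matrix(values_by_group))
    else table(factor(unlist(lapply(seq_along(values_by_group), function(i)
           rep(i, length(values_by_group[[i]]))))),
         factor(unlist(values_by_group)))
    if (any(dim(tab) < 2L))
      stop("variable '", variable,
           "': contingency table needs at least 2 levels per margin",
           call. = FALSE)
    expected <- suppressWarnings(chisq.test(tab, correct = FALSE))$expected
    if (any(expected < 5)) {
      test <- "fisher"; p <- fisher.test(tab)$p.value
    } else {
      test <- "chi_square"
      p <- suppressWarnings(chisq.test(tab, correct = FALSE))$p.value
    }
    summaries <- lapply(seq_len(nrow(tab)), function(i)
      list(kind = "count", counts = tab[i, ],
           label = paste(tab[i, ], collapse = "/")))
  }
  structure(list(variable = variable, kind = variable_kind,
                 summaries = summaries, test = test, p_value = p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s [%s]: %s vs %s, p = %.3g\n",
              x$variable, x$test, x$summaries[[1]]$label,
              x$summaries[[2]]$label, x$p_value))
  invisible(x)
}

#' Spearman rank correlation
#'
#' @param x,y paired numeric samples, n >= 3.
#' @return list: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("Spearman correlation needs at least 3 complete pairs",
         call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Spearman correlation undefined for constant input", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' ROC analysis of a continuous predictor against a binary label
#'
#' The AUROC is the Mann-Whitney probability that a randomly chosen
#' positive outranks a randomly chosen negative, with ties counted one
#' half; it is computed from midranks and therefore equals the exhaustive
#' pair-count statistic exactly. The 95% confidence interval uses the
#' Hanley-McNeil standard error with normal quantiles, clipped to
#' `[0, 1]`; the p value is the two-sided normal test of AUROC = 0.5 with
#' that standard error. The operating cutoff maximises Youden's J
#' (sensitivity + specificity - 1), with ties broken toward higher
#' specificity; subjects are classified positive when the (oriented)
#' predictor strictly exceeds the cutoff.
#'
#' @param predictor numeric predictor values.
#' @param labels logical (or 0/1) outcome labels; both classes required.
#' @param direction `"greater"` (default): higher predictor values indicate
#'   the positive class; `"less"`: lower values do.
#' @param conf_level confidence level for the interval.
#' @param predictor_name name carried into the summary.
#' @return a `roc_summary`: `auroc`, `ci_low`, `ci_high`, `p_value`,
#'   `optimal_cutoff`, `sensitivity`, `specificity`, `n_pos`, `n_neg`,
#'   `degenerate`.
#' @export
roc_analysis <- function(predictor, labels, direction = c("greater", "less"),
                         conf_level = 0.95, predictor_name = "predictor") {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- !is.na(predictor) & !is.na(labels)
  x <- as.numeric(predictor[ok]); y <- labels[ok]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L)
    stop("ROC analysis requires both outcome classes (",
         predictor_name, ")", call. = FALSE)
  if (direction == "less") x <- -x
  degenerate <- length(unique(x)) == 1L
  if (degenerate) {
    return(structure(list(predictor = predictor_name, auroc = 0.5,
                          ci_low = 0, ci_high = 1, p_value = 1,
                          optimal_cutoff = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_, n_pos = n1, n_neg = n0,
                          direction = direction, degenerate = TRUE),
                     class = "roc_summary"))
  }
  r <- rank(x)  # midranks: ties contribute 1/2 per pair
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # Hanley-McNeil asymptotic SE
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  p <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se) else
    as.numeric(auc == 0.5)
  # Youden-optimal cutoff over midpoints between consecutive unique values
  ux <- sort(unique(x))
  cand <- c(ux[1] - 1, (ux[-1] + ux[-length(ux)]) / 2)
  sens <- vapply(cand, function(cc) sum(x[y] > cc) / n1, numeric(1))
  spec <- vapply(cand, function(cc) sum(x[!y] <= cc) / n0, numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]  # ties -> higher specificity
  cutoff <- cand[best]
  if (direction == "less") cutoff <- -cutoff
  structure(list(predictor = predictor_name, auroc = auc,
                 ci_low = ci[1], ci_high = ci[2], p_value = p,
                 optimal_cutoff = cutoff, sensitivity = sens[best],
                 specificity = spec[best], n_pos = n1, n_neg = n0,
                 direction = direction, degenerate = FALSE),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf(
    "<roc_summary> %s: AUROC %.3f (95%% CI %.3f-%.3f), p = %.3g%s\n",
    x$predictor, x$auroc, x$ci_low, x$ci_high, x$p_value,
    if (x$degenerate) " [degenerate predictor]" else
      sprintf("; cutoff %.3g (sens %.2f, spec %.2f)", x$optimal_cutoff,
              x$sensitivity, x$specificity)))
  invisible(x)
}

#' ROC table over a predictor panel
#'
#' Runs [roc_analysis()] for every predictor column of a panel built by
#' [build_predictor_panel()] against the renal-impairment labels,
#' producing one summary row per predictor (baselines, each absolute and
#' relative burden, the renal-specific differential burden, and
#' preoperative creatinine). Constant predictors are retained and flagged
#' degenerate with AUROC 0.5.
#'
#' @param panel data.frame with `patient_id` and numeric predictor columns.
#' @param labels data.frame from [label_cohort()] (or logical vector
#'   aligned with `panel` rows).
#' @param direction passed to [roc_analysis()].
#' @return data.frame of ROC summaries, one row per predictor.
#' @export
roc_table <- function(panel, labels, direction = "greater") {
  if (is.data.frame(labels)) {
    i <- match(panel$patient_id, labels$patient_id)
    lab <- labels$impaired[i]
  } else lab <- as.logical(labels)
  if (sum(lab, na.rm = TRUE) < 2L || sum(!lab, na.rm = TRUE) < 2L)
    stop("ROC table requires at least 2 patients per outcome class",
         call. = FALSE)
  preds <- setdiff(names(panel), "patient_id")
  rows <- lapply(preds, function(pn) {
    v <- panel[[pn]]
    if (all(is.na(v))) return(NULL)
    s <- roc_analysis(v, lab, direction = direction, predictor_name = pn)
    data.frame(predictor = pn, auroc = s$auroc, ci_low = s$ci_low,
               ci_high = s$ci_high, p_value = s$p_value,
               optimal_cutoff = s$optimal_cutoff,
               sensitivity = s$sensitivity, specificity = s$specificity,
               n_pos = s$n_pos, n_neg = s$n_neg, degenerate = s$degenerate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
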