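#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computed from beta quantiles; the lower bound is exactly 0 when no
#' successes are observed and the upper bound exactly 1 when all trials
#' succeed.
#'
#' @param successes,trials Counts with `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param confidence Coverage level.
#' @return Named numeric vector `c(lower, upper)` of proportions.
#' @export
clopper_pearson <- function(successes, trials, confidence = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials ||
      successes != round(successes) || trials != round(trials)) {
    abort("invalid counts: need 0 <= successes <= trials, trials >= 1")
  }
  alpha <- 1 - confidence
  lower <- if (successes == 0) 0 else qbeta(alpha / 2, successes,
                                            trials - successes + 1)
  upper <- if (successes == trials) 1 else qbeta(1 - alpha / 2,
                                                 successes + 1,
                                                 trials - successes)
  c(lower = lower, upper = upper)
}

#' Diagnostic confusion metrics with exact binomial intervals
#'
#' Tabulates predicted against true labels for a designated positive label
#' and reports sensitivity and specificity with exact Clopper-Pearson 95%
#' confidence intervals. Percentages are reported rounded half away from
#' zero. When a class is absent the corresponding metric is flagged absent
#' (`NA`), not zero.
#'
#' @param predicted,truth Equal-length label vectors.
#' @param positive The positive label.
#' @param confidence Interval coverage.
#' @return A list of class `eval_report`: counts `tp`, `fn`, `tn`, `fp`,
#'   and `sensitivity`/`specificity` entries each holding `estimate`,
#'   `lower`, `upper`.
#' @export
confusion_metrics <- function(predicted, truth, positive,
                              confidence = 0.95) {
  if (length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must have equal length")
  }
  is_pos <- truth == positive
  pred_pos <- predicted == positive
  tp <- sum(is_pos & pred_pos)
  fn <- sum(is_pos & !pred_pos)
  tn <- sum(!is_pos & !pred_pos)
  fp <- sum(!is_pos & pred_pos)
  metric <- function(successes, trials) {
    if (trials == 0) {
      return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                  successes = successes, trials = trials))
    }
    ci <- clopper_pearson(successes, trials, confidence)
    list(estimate = successes / trials, lower = ci[["lower"]],
         upper = ci[["upper"]], successes = successes, trials = trials)
  }
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 positive = positive,
                 confidence = confidence,
                 sensitivity = metric(tp, tp + fn),
                 specificity = metric(tn, tn + fp)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(m, name) {
    if (is.na(m$estimate)) {
      cat(sprintf("  %s: undefined (no %s)\n", name,
                  ifelse(name == "sensitivity", "positives", "negatives")))
    } else {
      cat(sprintf("  %s: %d%% (%d/%d, 95%% CI %d%%-%d%%)\n", name,
                  round_half_up(100 * m$estimate), m$successes, m$trials,
                  round_half_up(100 * m$lower),
                  round_half_up(100 * m$upper)))
    }
  }
  cat("<eval_report> positive =", x$positive, "\n")
  cat(sprintf("  tp=%d fn=%d tn=%d fp=%d\n", x$tp, x$fn, x$tn, x$fp))
  fmt(x$sensitivity, "sensitivity")
  fmt(x$specificity, "specificity")
  invisible(x)
}

#' @describeIn confusion_metrics Metrics as a tidy tibble (one row per
#'   metric).
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) {
  row <- function(name, m) {
    tibble::tibble(metric = name, estimate = m$estimate,
                   conf.low = m$lower, conf.high = m$upper,
                   successes = m$successes, trials = m$trials)
  }
  dplyr::bind_rows(row("sensitivity", x$sensitivity),
                   row("specificity", x$specificity))
}

#' @describeIn confusion_metrics One-row summary.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(tp = x$tp, fn = x$fn, tn = x$tn, fp = x$fp,
                 sensitivity = x$sensitivity$estimate,
                 specificity = x$specificity$estimate)
}

#' ROC area under the curve with bootstrap confidence interval
#'
#' AUC via the pairwise-concordance (Mann-Whitney) formulation -- the
#' probability that a random positive scores above a random negative, ties
#' counted one half -- which makes it invariant under strictly monotone
#' transforms of the scores. The confidence interval is a stratified
#' bootstrap percentile interval (resampling positives and negatives
#' separately); seed the RNG for reproducibility.
#'
#' @param scores Numeric score vector.
#' @param labels Label vector; `positive` designates the positive class.
#' @param positive Positive label.
#' @param n_boot Bootstrap resamples (0 to skip the interval).
#' @param confidence Interval coverage.
#' @return A list: `auc`, `lower`, `upper`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive, n_boot = 2000,
                    confidence = 0.95) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("both classes must be present")
  }
  auc_fun <- function(p, n) {
    r <- rank(c(p, n))
    (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
      (length(p) * length(n))
  }
  auc <- auc_fun(pos, neg)
  lower <- upper <- NA_real_
  if (n_boot > 0) {
    boots <- vapply(seq_len(n_boot), function(i) {
      auc_fun(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    }, numeric(1))
    alpha <- 1 - confidence
    qs <- quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lower <- qs[1]
    upper <- qs[2]
  }
  list(auc = auc, lower = lower, upper = upper,
       n_pos = length(pos), n_neg = length(neg))
}

#' Coefficient of variation over a fixed score range
#'
#' Replicate variability of panel classification scores expressed as the
#' sample standard deviation divided by the observed overall score range of
#' the panel -- scores live on an interval scale whose zero is arbitrary,
#' so a plain SD/mean CV would be meaningless.
#'
#' @param scores Numeric vector of replicate scores (>= 2).
#' @param score_range Length-2 numeric `c(lo, hi)`, `hi > lo`.
#' @return The CV as a fraction.
#' @export
cv_over_range <- function(scores, score_range) {
  if (length(scores) < 2) abort("need >= 2 replicate scores")
  if (diff(score_range) <= 0) abort("degenerate score range")
  sd(scores) / (score_range[2] - score_range[1])
}

# Spearman rank correlation with Fisher-z CI and two-sided p (t
# approximation via cor.test).
spearman_with_ci <- function(x, y, conf = 0.95) {
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  rho <- unname(ct$estimate)
  ci <- fisher_z_ci(rho, length(x), conf)
  list(rho = rho, lower = ci[["lower"]], upper = ci[["upper"]],
       p = ct$p.value)
}

#' Time-dependent stability analysis of replicate scores
#'
#' Quantifies drift of panel scores over bench time: Spearman rank
#' correlation between time and score (with Fisher-z 95% CI and two-sided
#' p) and the ordinary least-squares slope in score units per hour.
#' Optionally reports the replicate CV over a fixed score range.
#'
#' @param times Numeric times (hours).
#' @param scores Numeric scores (a.u.), same length (>= 4 pairs).
#' @param score_range Optional `c(lo, hi)` for CV reporting.
#' @return A list of class `stability_report`: `rho`, `rho_lower`,
#'   `rho_upper`, `p`, `slope`, `cv`, `n`, `degenerate`.
#' @export
stability_analysis <- function(times, scores, score_range = NULL) {
  if (length(times) != length(scores) || length(times) < 4) {
    abort("need >= 4 paired (time, score) points")
  }
  degenerate <- sd(scores) == 0
  if (degenerate) {
    res <- list(rho = NA_real_, lower = NA_real_, upper = NA_real_,
                p = NA_real_)
    slope <- 0
  } else {
    res <- spearman_with_ci(times, scores)
    slope <- unname(coef(lm(scores ~ times))[2])
  }
  cv <- if (!is.null(score_range)) cv_over_range(scores, score_range)
        else NA_real_
  structure(list(rho = res$rho, rho_lower = res$lower,
                 rho_upper = res$upper, p = res$p, slope = slope,
                 cv = cv, n = length(times), degenerate = degenerate),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> n =", x$n, "\n")
  if (x$degenerate) {
    cat("  constant scores: rho undefined, slope 0\n")
  } else {
    cat(sprintf("  Spearman rho %.3f (95%% CI %.3f to %.3f), p = %.4f\n",
                x$rho, x$rho_lower, x$rho_upper, x$p))
    cat(sprintf("  slope %.4f a.u./hour\n", x$slope))
  }
  if (!is.na(x$cv)) cat(sprintf("  CV over range: %.1f%%\n", 100 * x$cv))
  invisible(x)
}

#' @describeIn stability_analysis One-row tidy summary.
#' @param x A `stability_report`.
#' @param ... Unused.
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(rho = x$rho, rho_lower = x$rho_lower,
                 rho_upper = x$rho_upper, p = x$p, slope = x$slope,
                 cv = x$cv, n = x$n)
}

#' Rank correlation of panel scores with an ordinal staging variable
#'
#' Spearman correlation of classification scores with ordinal tumour-stage
#' (or risk-score) codes, with Fisher-z confidence interval and two-sided
#' p-value.
#'
#' @param scores Numeric panel scores.
#' @param stages Ordinal stage codes (numeric or ordered factor), same
#'   length (>= 4 pairs).
#' @param confidence Interval coverage.
#' @return A list: `rho`, `lower`, `upper`, `p`, `n`.
#' @export
rank_correlation_vs_staging <- function(scores, stages, confidence = 0.95) {
  if (length(scores) != length(stages) || length(scores) < 4) {
    abort("need >= 4 paired (score, stage) points")
  }
  stages <- as.numeric(stages)
  res <- spearman_with_ci(stages, scores, confidence)
  c(res, list(n = length(scores)))
}
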