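# Prediction metrics with bootstrap uncertainty, naive baselines, Pearson
# correlation on ordered pairs, and the no-intercept random-slope
# mixed-effects analysis with likelihood-ratio tests.

#' Rank-based AUC
#'
#' Area under the ROC curve computed from midranks, so tied scores receive
#' half credit; identical to the normalised Mann-Whitney U statistic. With
#' constant scores and both classes present the value is exactly 0.5,
#' matching the naive majority/coin-flip baseline for balanced ordering
#' pairs.
#'
#' @param labels vector in `{0, 1}`; both classes must be present.
#' @param scores numeric vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC requires both classes in `labels`")
  rk <- rank(scores) # midranks -> half credit for ties
  (sum(rk[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Resamples the test set with replacement `n_boot` times (default 1,000)
#' and returns the percentile interval of the resampled AUCs; resamples
#' that lose a class are redrawn.
#'
#' @inheritParams auc
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level (default 0.95).
#' @param seed integer seed for the resampling.
#' @return list with `auc` (point estimate), `lower`, `upper`, `n_boot`.
#' @export
bootstrap_auc_ci <- function(labels, scores, n_boot = 1000L, level = 0.95,
                             seed = 1L) {
  point <- auc(labels, scores) # also validates input
  set.seed(seed)
  n <- length(labels)
  stat <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2) break
    }
    stat[b] <- auc(labels[idx], scores[idx])
  }
  qs <- stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(auc = point, lower = qs[1], upper = qs[2], n_boot = n_boot)
}

#' Regression metrics and the naive-zero baseline
#'
#' `regression_metrics()` returns RMSE, MAE and the coefficient of
#' determination (relative to the mean of `y`). `naive_zero_metrics()`
#' evaluates the baseline that always predicts 0, the mean of a balanced
#' change target.
#'
#' @param y observed values (length at least 2).
#' @param y_hat predictions.
#' @return list with `rmse`, `mae`, `r_squared`.
#' @export
regression_metrics <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat))
  if (length(y) < 2) stop("need at least 2 observations")
  err <- y - y_hat
  sst <- sum((y - mean(y))^2)
  list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
       r_squared = if (sst > 0) 1 - sum(err^2) / sst else NA_real_)
}

#' @rdname regression_metrics
#' @export
naive_zero_metrics <- function(y) regression_metrics(y, rep(0, length(y)))

#' Pearson correlation on chronologically ordered pairs
#'
#' Correlation analyses of predicted change use only pairs presented in
#' chronological order (positive time difference); for ordering-task
#' models the presigmoid logit is the prediction. This helper checks the
#' ordering restriction and returns the correlation with its two-sided
#' t-distribution p-value. p-values below 1e-16 are formatted as
#' `"<1e-16"` in the print method.
#'
#' @param targets ground-truth change values for ordered pairs.
#' @param predictions predicted change (or logit) values.
#' @param delta_time optional vector of the pairs' time differences; when
#'   given, pairs with non-positive `delta_time` are dropped before the
#'   correlation.
#' @return list of class `lilac_pcc` with `r`, `p`, `n`.
#' @export
pearson_ordered <- function(targets, predictions, delta_time = NULL) {
  stopifnot(length(targets) == length(predictions))
  if (!is.null(delta_time)) {
    keep <- delta_time > 0
    targets <- targets[keep]
    predictions <- predictions[keep]
  }
  if (stats::sd(targets) == 0 || stats::sd(predictions) == 0)
    stop("zero variance in targets or predictions")
  ct <- stats::cor.test(targets, predictions, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 n = length(targets)),
            class = "lilac_pcc")
}

#' @export
print.lilac_pcc <- function(x, ...) {
  p <- if (x$p < 1e-16) "<1e-16" else format(x$p, digits = 3)
  cat(sprintf("Pearson r = %.3f (P %s%s, n = %d ordered pairs)\n", x$r,
              if (x$p < 1e-16) "" else "= ", p, x$n))
  invisible(x)
}

#' Ordering-task evaluation report
#'
#' AUC with its bootstrap confidence interval, plus the naive baseline
#' (constant score), which is exactly 0.5 for tie-aware rank AUC.
#'
#' @param labels order labels in `{0, 1}`.
#' @param scores comparison logits (or probabilities).
#' @param n_boot,level,seed bootstrap settings, see [bootstrap_auc_ci()].
#' @return list of class `eval_report`.
#' @export
evaluate_ordering <- function(labels, scores, n_boot = 1000L, level = 0.95,
                              seed = 1L) {
  ci <- bootstrap_auc_ci(labels, scores, n_boot, level, seed)
  structure(list(task = "ordering", auc = ci$auc, ci = c(ci$lower, ci$upper),
                 naive_auc = auc(labels, rep(0, length(labels))),
                 n = length(labels)),
            class = "eval_report")
}

#' Regression-task evaluation report
#'
#' Model metrics side by side with the naive always-zero baseline, plus
#' the Pearson correlation restricted to chronologically ordered pairs.
#'
#' @param y observed change values.
#' @param y_hat predicted change values.
#' @param delta_time the pairs' time differences (for the ordered-pair
#'   correlation); defaults to `y` for interval tasks.
#' @return list of class `eval_report`.
#' @export
evaluate_regression <- function(y, y_hat, delta_time = y) {
  m <- regression_metrics(y, y_hat)
  structure(list(task = "regression", rmse = m$rmse, mae = m$mae,
                 r_squared = m$r_squared, naive = naive_zero_metrics(y),
                 pcc = pearson_ordered(y, y_hat, delta_time),
                 n = length(y)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  if (x$task == "ordering") {
    cat(sprintf("AUC %.4f (95%% bootstrap CI [%.4f, %.4f], n = %d); naive %.2f\n",
                x$auc, x$ci[1], x$ci[2], x$n, x$naive_auc))
  } else {
    cat(sprintf("RMSE %.3f  MAE %.3f  R2 %.3f (n = %d); naive-zero RMSE %.3f\n",
                x$rmse, x$mae, x$r_squared, x$n, x$naive$rmse))
    print(x$pcc)
  }
  invisible(x)
}

#' Anchored change rows for mixed-effects analysis
#'
#' Builds, for every subject, the pairs anchoring each later timepoint to
#' the subject's first timepoint (where observed and predicted change are
#' zero by construction), the form the slope analysis expects.
#'
#' @param pairs a `lilac_pairs` object.
#' @return a `lilac_pairs` object containing only (first, t) pairs in
#'   chronological presentation order.
#' @export
anchored_pairs <- function(pairs) {
  rec <- pairs$records
  keep_rows <- lapply(split(seq_len(nrow(rec)), rec$subject_id), function(rows) {
    first <- rows[which.min(rec$time[rows])]
    later <- setdiff(rows, first)
    data.frame(i = first, j = later)
  })
  df <- do.call(rbind, keep_rows)
  rownames(df) <- NULL
  df$subject_id <- rec$subject_id[df$i]
  df$delta_time <- rec$time[df$j] - rec$time[df$i]
  df$order_label <- as.integer(df$delta_time > 0)
  df$delta_target <- rec$target[df$j] - rec$target[df$i]
  pairs$pairs <- df
  pairs
}

#' No-intercept random-slope mixed-effects analysis of predicted change
#'
#' Fits, by maximum likelihood, the model
#' `change = beta * time + gamma * group * time + b_subject * time + e`,
#' with no intercepts (change from each subject's first timepoint is zero
#' at time 0 by construction) and a subject-level random slope
#' `b_subject ~ N(0, sigma_b^2)`. Individual variability is tested by a
#' likelihood-ratio test against the model without the random slope,
#' using the boundary-corrected null mixture `0.5 chi^2_0 + 0.5 chi^2_1`
#' (the variance is tested on its boundary). When a group is supplied,
#' the group-by-time effect is tested by a likelihood-ratio test against
#' the random-slope model without the group term (chi^2 with 1 df).
#'
#' @param data data frame with columns `subject` (id), `time` (time from
#'   the subject's first timepoint, positive), `change` (predicted or
#'   observed change from baseline) and optionally `group` (two levels;
#'   the second level carries the `gamma` effect).
#' @return object of class `lilac_lme`: list with `slope` (beta),
#'   `group_effect` (gamma or `NA`), `sigma_b2`, `sigma_e2`, `lrt_random`
#'   and `lrt_group` (each a list with `stat`, `p`), `converged`, `n_subjects`.
#' @export
lme_fit <- function(data) {
  stopifnot(all(c("subject", "time", "change") %in% names(data)))
  if (length(unique(data$subject)) < 3)
    stop("mixed-effects slope analysis needs at least 3 subjects")
  has_group <- "group" %in% names(data)
  if (has_group) {
    lv <- sort(unique(as.character(data$group)))
    if (length(lv) != 2) stop("`group` must have exactly two levels")
    data$grp <- as.numeric(as.character(data$group) == lv[2])
  }

  converged <- TRUE
  note_nonconv <- function(w) {
    if (grepl("converge|singular", conditionMessage(w), ignore.case = TRUE))
      converged <<- FALSE
    invokeRestart("muffleWarning")
  }
  fit_lmer <- function(formula) {
    withCallingHandlers(
      suppressMessages(lme4::lmer(formula, data = data, REML = FALSE)),
      warning = note_nonconv)
  }

  full <- if (has_group) {
    fit_lmer(change ~ 0 + time + time:grp + (0 + time | subject))
  } else {
    fit_lmer(change ~ 0 + time + (0 + time | subject))
  }
  fixed <- lme4::fixef(full)
  vc <- as.data.frame(lme4::VarCorr(full))
  sigma_b2 <- vc$vcov[vc$grp == "subject"][1]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"][1]

  # random-slope LRT vs the fixed-effects-only reduction
  reduced_fe <- if (has_group) {
    stats::lm(change ~ 0 + time + time:grp, data = data)
  } else {
    stats::lm(change ~ 0 + time, data = data)
  }
  stat_r <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                          as.numeric(stats::logLik(reduced_fe))))
  p_r <- if (stat_r <= 0) 1 else
    0.5 * stats::pchisq(stat_r, df = 1, lower.tail = FALSE)

  lrt_group <- NULL
  if (has_group) {
    no_group <- fit_lmer(change ~ 0 + time + (0 + time | subject))
    stat_g <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                            as.numeric(stats::logLik(no_group))))
    lrt_group <- list(stat = stat_g,
                      p = stats::pchisq(stat_g, df = 1, lower.tail = FALSE))
  }

  structure(list(slope = unname(fixed["time"]),
                 group_effect = if (has_group)
                   unname(fixed["time:grp"]) else NA_real_,
                 sigma_b2 = sigma_b2, sigma_e2 = sigma_e2,
                 lrt_random = list(stat = stat_r, p = p_r),
                 lrt_group = lrt_group, converged = converged,
                 n_subjects = length(unique(data$subject))),
            class = "lilac_lme")
}

#' @export
print.lilac_lme <- function(x, ...) {
  cat(sprintf("LME (no intercept, random subject slopes, ML; %d subjects)\n",
              x$n_subjects))
  cat(sprintf("  slope %.4f  random-slope var %.4g  (LRT stat %.2f, p %s)\n",
              x$slope, x$sigma_b2, x$lrt_random$stat,
              format.pval(x$lrt_random$p, digits = 3)))
  if (!is.null(x$lrt_group))
    cat(sprintf("  group x time effect %.4f  (LRT stat %.2f, p %s)\n",
                x$group_effect, x$lrt_group$stat,
                format.pval(x$lrt_group$p, digits = 3)))
  if (!x$converged) cat("  [fit flagged: convergence/singularity warning]\n")
  invisible(x)
}

#' Simulate anchored-change slope data
#'
#' Draws per-subject slopes `beta + gamma * group + b_i` with
#' `b_i ~ N(0, sigma_b^2)` and observations
#' `change = slope_i * time + e`, `e ~ N(0, sigma_e^2)`, in the anchored
#' form used by [lme_fit()]. Used for parameter-recovery and
#' operating-characteristic checks of the slope analysis.
#'
#' @param n_subjects total subjects (split half/half into groups when
#'   `gamma` is not `NA`).
#' @param times positive time offsets from baseline shared by all subjects.
#' @param beta fixed slope.
#' @param gamma group slope difference; `NA` simulates without groups.
#' @param sigma_b random-slope standard deviation.
#' @param sigma_e residual standard deviation.
#' @return data frame with columns `subject`, `time`, `change` and
#'   (when grouped) `group`.
#' @export
simulate_slope_data <- function(n_subjects = 40L, times = 1:5, beta = 1,
                                gamma = NA, sigma_b = 0.15, sigma_e = 0.3) {
  grouped <- !is.na(gamma)
  group <- if (grouped)
    rep(c("control", "treatment"), length.out = n_subjects)
  else rep(NA_character_, n_subjects)
  slopes <- beta + (if (grouped) gamma * (group == "treatment") else 0) +
    stats::rnorm(n_subjects, 0, sigma_b)
  df <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    data.frame(subject = sprintf("S%03d", i), time = times,
               change = slopes[i] * times +
                 stats::rnorm(length(times), 0, sigma_e),
               group = group[i])
  }))
  if (!grouped) df$group <- NULL
  df
}
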