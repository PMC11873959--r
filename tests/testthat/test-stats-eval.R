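test_that("rank AUC matches brute-force pair counting and handles ties", {
  labels <- c(1, 1, 0, 0)
  scores <- c(0.9, 0.4, 0.6, 0.1)
  # brute force over the 4 positive-negative pairs: 3 wins / 4
  expect_equal(auc(labels, scores), 0.75)
  expect_equal(auc(c(0, 1), c(0.1, 0.9)), 1)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5) # constant scores
  expect_error(auc(c(1, 1), c(0.2, 0.3)), "both classes")

  brute <- function(labels, scores) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    wins <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    mean(wins)
  }
  set.seed(1)
  for (trial in 1:10) {
    n <- 200
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n, mean = labels), 1) # rounded -> many ties
    expect_equal(auc(labels, scores), brute(labels, scores))
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  labels <- rbinom(150, 1, 0.5)
  scores <- rnorm(150, mean = 0.8 * labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc(labels, scores), ref, tolerance = 1e-12)
})

test_that("bootstrap CI brackets the point estimate and shrinks with n", {
  set.seed(3)
  labels <- rbinom(80, 1, 0.5)
  scores <- rnorm(80, mean = labels)
  ci <- bootstrap_auc_ci(labels, scores, n_boot = 300, seed = 1)
  expect_lte(ci$lower, ci$auc)
  expect_gte(ci$upper, ci$auc)
  ci_same <- bootstrap_auc_ci(labels, scores, n_boot = 300, seed = 1)
  expect_identical(ci, ci_same)

  widths <- vapply(1:4, function(s) {
    set.seed(s)
    small <- sample(80, 30)
    w_small <- with(bootstrap_auc_ci(labels[small], scores[small],
                                     n_boot = 200, seed = s),
                    upper - lower)
    big_l <- rbinom(400, 1, 0.5)
    big_s <- rnorm(400, mean = big_l)
    w_big <- with(bootstrap_auc_ci(big_l, big_s, n_boot = 200, seed = s),
                  upper - lower)
    w_big < w_small
  }, TRUE)
  expect_gte(mean(widths), 0.75)
})

test_that("regression metrics match hand arithmetic", {
  m <- regression_metrics(c(0, 2, 4), c(1, 2, 3))
  expect_equal(m$rmse, sqrt(2 / 3))
  expect_equal(m$mae, 2 / 3)
  expect_equal(regression_metrics(c(1, 2), c(1, 2))$rmse, 0)
  expect_equal(regression_metrics(c(1, 2), c(1, 2))$r_squared, 1)
  nz <- naive_zero_metrics(c(1, -1))
  expect_equal(nz$rmse, 1)
  expect_equal(nz$mae, 1)
  expect_error(regression_metrics(1, 1), "at least 2")

  set.seed(4)
  for (trial in 1:5) {
    y <- rnorm(20); yh <- rnorm(20)
    mm <- regression_metrics(y, yh)
    expect_gte(mm$rmse, mm$mae)
  }
})

test_that("ordered-pair Pearson correlation matches closed forms", {
  expect_equal(pearson_ordered(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_ordered(c(1, 2, 3), c(-1, -2, -3))$r, -1)
  expect_equal(pearson_ordered(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  # non-positive delta_time rows are excluded before correlating
  p <- pearson_ordered(c(9, 1, 2, 3), c(0, 1, 3, 2), c(-5, 1, 2, 3))
  expect_equal(p$r, 0.5)
  expect_equal(p$n, 3)
  expect_error(pearson_ordered(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("evaluation reports wire metrics and baselines together", {
  set.seed(5)
  labels <- rbinom(60, 1, 0.5)
  scores <- rnorm(60, mean = 2 * labels - 1)
  rep_o <- evaluate_ordering(labels, scores, n_boot = 100, seed = 2)
  expect_equal(rep_o$naive_auc, 0.5)
  expect_lte(rep_o$ci[1], rep_o$auc)
  expect_gte(rep_o$ci[2], rep_o$auc)

  y <- rnorm(30, sd = 2); yh <- y + rnorm(30, sd = 0.3)
  rep_r <- evaluate_regression(y, yh, delta_time = rep(1, 30))
  expect_lt(rep_r$rmse, rep_r$naive$rmse)
  expect_gt(rep_r$pcc$r, 0.9)
})

test_that("the slope model recovers simulated fixed and random effects", {
  set.seed(6)
  d <- simulate_slope_data(n_subjects = 40, times = 1:5, beta = 1,
                           gamma = 0.4, sigma_b = 0.2, sigma_e = 0.3)
  f <- lme_fit(d)
  expect_lt(abs(f$slope - 1) / 1, 0.2)
  expect_lt(abs(f$group_effect - 0.4) / 0.4, 0.35)
  expect_gt(f$sigma_b2, 0)
  expect_lt(f$lrt_random$p, 0.01) # clear individual variability
  expect_lt(f$lrt_group$p, 0.01)
  expect_true(all(c(f$lrt_random$p, f$lrt_group$p) >= 0))
})

test_that("degenerate shared slopes give a boundary random-effect test", {
  set.seed(7)
  d <- simulate_slope_data(n_subjects = 10, times = 1:4, beta = 1,
                           gamma = NA, sigma_b = 0, sigma_e = 0.1)
  f <- lme_fit(d)
  expect_lt(f$sigma_b2, 1e-3)
  expect_gt(f$lrt_random$p, 0.05) # no evidence of individual variability
  expect_true(is.na(f$group_effect))
  expect_error(lme_fit(data.frame(subject = c("a", "b"), time = 1,
                                  change = 1)), "3 subjects")
})

test_that("anchored pairs start every subject at its first timepoint", {
  rec <- data.frame(subject_id = rep(c("a", "b"), each = 3),
                    time = c(0, 2, 5, 1, 4, 6), path = NA,
                    target = c(0, 1, 2, 0, 2, 3))
  set.seed(8)
  anch <- anchored_pairs(make_pairs(rec, "interval"))
  expect_equal(nrow(anch$pairs), 4) # two later points per subject
  expect_true(all(anch$pairs$delta_time > 0))
  expect_equal(anch$pairs$i, rep(c(1L, 4L), each = 2)) # first timepoints
})
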