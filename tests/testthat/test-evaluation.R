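test_that("AUC: separable scores give 1, constant scores give 1/2", {
  y <- rep(c(0, 1), each = 10)
  expect_equal(auc_mann_whitney(c(rnorm(10, -5), rnorm(10, 5)), y), 1)
  expect_equal(auc_mann_whitney(rep(3, 20), y), 0.5)
  expect_error(auc_mann_whitney(rnorm(5), rep(1, 5)), "classes")
})

test_that("AUC equals the explicit double-loop pair count", {
  set.seed(30)
  s <- round(rnorm(30), 1)   # rounding forces some ties
  y <- rbinom(30, 1, 0.5); y[1] <- 1; y[2] <- 0
  a <- auc_mann_whitney(s, y)
  num <- 0; den <- 0
  for (i in which(y == 1)) for (j in which(y == 0)) {
    den <- den + 1
    num <- num + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  expect_equal(a, num / den, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(31)
  s <- rnorm(40); y <- rep(c(0, 1), 20)
  a <- auc_mann_whitney(s, y)
  expect_equal(auc_mann_whitney(exp(s), y), a, tolerance = 1e-12)
  expect_equal(auc_mann_whitney(3 * s - 7, y), a, tolerance = 1e-12)
})

test_that("DeLong AUC and CI agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  for (i in 1:3) {
    s <- rnorm(60); y <- rep(c(0, 1), 30)
    ours <- delong_ci(s, y)
    ref <- suppressMessages(pROC::ci.auc(
      pROC::roc(y, s, quiet = TRUE, direction = "<"), method = "delong"))
    expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-9)
    expect_equal(ours$ci_low, as.numeric(ref[1]), tolerance = 1e-6)
    expect_equal(ours$ci_high, as.numeric(ref[3]), tolerance = 1e-6)
  }
})

test_that("DeLong variance scales like 1/n and flags perfect separation", {
  set.seed(33)
  s <- rnorm(100); y <- rep(c(0, 1), 50)
  v1 <- delong_ci(s, y)$se^2
  v2 <- delong_ci(rep(s, 2), rep(y, 2))$se^2
  expect_lt(abs(v2 - v1 / 2) / (v1 / 2), 0.25)
  sep <- delong_ci(c(rnorm(20, -9), rnorm(20, 9)), rep(c(0, 1), each = 20))
  expect_true(sep$degenerate)
})

test_that("paired DeLong test: self-comparison and monotone maps give p = 1", {
  set.seed(34)
  s <- rnorm(50); y <- rep(c(0, 1), 25)
  self <- delong_paired_test(s, s, y)
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 1)
  mono <- delong_paired_test(s, plogis(2 * s + 1), y)
  expect_equal(mono$p_value, 1)
  expect_error(delong_paired_test(s, s[-1], y), "same cases")
  skip_if_not_installed("pROC")
  s2 <- s + rnorm(50, 0, 0.8)
  ours <- delong_paired_test(s, s2, y)
  ref <- suppressMessages(pROC::roc.test(
    pROC::roc(y, s, quiet = TRUE, direction = "<"),
    pROC::roc(y, s2, quiet = TRUE, direction = "<"),
    method = "delong", paired = TRUE))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("operating point equals the exhaustive-cutoff oracle", {
  set.seed(35)
  s <- rnorm(40); y <- rbinom(40, 1, plogis(s)); y[1] <- 1; y[2] <- 0
  op <- operating_point(s, y, n_bootstrap = 50, seed = 2)
  # oracle: scan every midpoint (plus one below the minimum)
  u <- sort(unique(s))
  cuts <- c(min(u) - 1, (u[-1] + u[-length(u)]) / 2)
  best <- -Inf; best_stats <- NULL
  for (ct in cuts) {
    pred <- s > ct
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    if (sens + spec - 1 > best + 1e-12) {
      best <- sens + spec - 1
      best_stats <- c(ct, sens, spec, mean(pred == (y == 1)))
    }
  }
  expect_equal(op$cutoff, best_stats[1])
  expect_equal(op$sensitivity, best_stats[2])
  expect_equal(op$specificity, best_stats[3])
  expect_equal(op$accuracy, best_stats[4])
  # accuracy re-derived from the confusion matrix at the chosen cutoff
  pred <- s > op$cutoff
  expect_equal(op$accuracy,
               (sum(pred & y == 1) + sum(!pred & y == 0)) / length(y))
})

test_that("a perfect classifier reaches sensitivity = specificity = 1", {
  y <- rep(c(0, 1), each = 15)
  op <- operating_point(c(rnorm(15, -4), rnorm(15, 4)), y,
                        n_bootstrap = 50, seed = 1)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  expect_equal(op$accuracy, 1)
})

test_that("calibration: well-calibrated, degenerate and anti-calibrated inputs", {
  set.seed(36)
  p <- runif(5000)
  y <- rbinom(5000, 1, p)
  cal <- calibration_curve(p, y)
  expect_lt(max(abs(cal$groups$observed - cal$groups$predicted)), 0.05)
  # constant probability at prevalence collapses to a single point
  y2 <- rbinom(400, 1, 0.3)
  cal2 <- calibration_curve(rep(mean(y2), 400), y2)
  expect_equal(nrow(cal2$groups), 1)
  expect_equal(cal2$groups$predicted, mean(y2))
  expect_equal(cal2$groups$observed, mean(y2))
  # flipped probabilities are maximally miscalibrated: the observed rate
  # mirrors the prediction (observed == 1 - predicted)
  cal3 <- calibration_curve(1 - y2, y2)
  expect_equal(cal3$groups$observed, 1 - cal3$groups$predicted,
               tolerance = 1e-12)
  expect_gt(max(abs(cal3$groups$observed - cal3$groups$predicted)), 0.4)
  expect_warning(calibration_curve(runif(5), rbinom(5, 1, 0.5),
                                   n_groups = 10), "fewer")
})

test_that("decision curve matches the net-benefit formula cell by cell", {
  set.seed(37)
  p <- runif(200); y <- rbinom(200, 1, p)
  grid <- c(0.1, 0.25, 0.5, 0.6, 0.9)
  dc <- decision_curve(p, y, grid)
  for (i in seq_along(grid)) {
    pt <- grid[i]
    pred <- p >= pt
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    expect_equal(dc$net_benefit[i],
                 tp / 200 - fp / 200 * pt / (1 - pt), tolerance = 1e-12)
  }
  # treat-all crosses zero exactly at the prevalence
  prev <- mean(y)
  ta <- function(pt) prev - (1 - prev) * pt / (1 - pt)
  expect_equal(ta(prev), 0, tolerance = 1e-12)
  expect_true(all(dc$treat_none == 0))
  # a model that calls everyone positive approaches prevalence as pt -> 0
  dc2 <- decision_curve(rep(1, 200), y, 0.001)
  expect_equal(dc2$net_benefit, prev, tolerance = 1e-2)
  expect_error(decision_curve(p, y, c(0, 0.5)), "strictly")
})

test_that("net benefit never exceeds the perfect classifier's", {
  set.seed(38)
  p <- runif(300); y <- rbinom(300, 1, p)
  grid <- seq(0.05, 0.95, by = 0.05)
  dc_model <- decision_curve(p, y, grid)
  dc_perfect <- decision_curve(as.numeric(y), y, grid)
  expect_true(all(dc_model$net_benefit <= dc_perfect$net_benefit + 1e-12))
})

test_that("chi-square reproduces the cohort-split comparison and the oracle", {
  # 75/92 vs 22/34 positives by cohort
  res <- chi_square_2x2(75, 92, 22, 34)
  expect_equal(round(res$p_value, 3), 0.463)
  # exactly proportional rows are independent
  res0 <- chi_square_2x2(10, 20, 30, 60)
  expect_equal(res0$chi2, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)
  # random table vs scalar-loop expected-count oracle
  set.seed(39)
  tab <- matrix(rpois(4, 30) + 1, 2)
  res1 <- chi_square_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  chi <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / sum(tab)
    chi <- chi + (tab[i, j] - e)^2 / e
  }
  expect_equal(res1$chi2, chi, tolerance = 1e-12)
  expect_error(chi_square_2x2(0, 0, 3, 4), "margins")
})

test_that("Welch t test: identical groups, hand-computed 5+5, large effects", {
  x <- c(1, 2, 3, 4, 5)
  res <- two_sample_t(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  a <- c(2.1, 3.4, 1.9, 4.0, 2.8); b <- c(5.2, 4.9, 6.1, 5.5, 4.7)
  res2 <- two_sample_t(a, b)
  va <- var(a) / 5; vb <- var(b) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 4 + vb^2 / 4)
  expect_equal(res2$t, t_hand, tolerance = 1e-12)
  expect_equal(res2$df, df_hand, tolerance = 1e-12)
  set.seed(40)
  res3 <- two_sample_t(rnorm(200, 1), rnorm(200, 0))
  expect_lt(res3$p_value, 1e-10)
  res4 <- two_sample_t(rep(2, 5), rep(2, 5))
  expect_equal(res4$p_value, 1)
})
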