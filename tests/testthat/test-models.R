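test_that("intercept-only fit reproduces the log-odds of the prevalence", {
  y <- rep(c(1, 0), c(30, 70))
  fit <- fit_logistic(matrix(numeric(0), 100, 0), y)
  expect_equal(fit$intercept, log(0.3 / 0.7), tolerance = 1e-8)
})

test_that("logistic ML estimates agree with glm on a moderate design", {
  set.seed(12)
  x <- matrix(rnorm(600), 300, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(300, 1, plogis(-0.5 + x[, 1] - 0.7 * x[, 2]))
  fit <- fit_logistic(x, y)
  ref <- glm(y ~ a + b, data = as.data.frame(x), family = binomial())
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$cov))),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
})

test_that("separation triggers the ridge fallback with finite coefficients", {
  x <- matrix(c(-2, -1, -0.5, 0.5, 1, 2), 6, 1,
              dimnames = list(NULL, "x"))
  y <- c(0, 0, 0, 1, 1, 1)
  expect_warning(fit <- fit_logistic(x, y), "separation")
  expect_true(fit$separation)
  expect_true(all(is.finite(c(fit$intercept, fit$coefficients))))
  expect_error(fit_logistic(x, rep(1, 6)), "single class")
  expect_error(fit_logistic(cbind(x, x2 = 2 * x[, 1]), y), "collinear")
})

test_that("rad_score is the linear predictor and links to probability", {
  set.seed(13)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(100, 1, plogis(x[, 1]))
  fit <- fit_logistic(x, y)
  sc <- rad_score(fit, x)
  expect_equal(sc, fit$intercept + drop(x %*% fit$coefficients),
               tolerance = 1e-12)
  # all-zero feature vector scores exactly the intercept
  expect_equal(rad_score(fit, c(a = 0, b = 0)), fit$intercept)
  # sigmoid of the score is the fitted probability
  expect_equal(plogis(sc), unname(fit$fitted), tolerance = 1e-9)
  # monotone in a positive-coefficient feature
  stopifnot(fit$coefficients[["a"]] > 0)
  x2 <- x; x2[, "a"] <- x2[, "a"] + 1
  expect_true(all(rad_score(fit, x2) > sc))
  expect_error(rad_score(fit, x[, "a", drop = FALSE]), "missing")
})

test_that("univariate odds ratio matches the 2x2 cross-product identity", {
  # ER-negative/positive by outcome counts from the cohort table:
  # outcome-positive: 39 ER-neg, 58 ER-pos; outcome-negative: 14, 112
  er <- factor(rep(c("negative", "positive", "negative", "positive"),
                   c(39, 58, 14, 112)), levels = c("negative", "positive"))
  y <- rep(c(1, 1, 0, 0), c(39, 58, 14, 112))
  res <- univariate_odds(er, y)
  # odds of outcome given ER-positive over ER-negative
  expect_equal(res$or, (58 * 14) / (39 * 112), tolerance = 1e-6)
  expect_true(res$ci_low <= res$or && res$or <= res$ci_high)
  # inverted coding reproduces the reciprocal cross-product 5.379
  expect_equal(1 / res$or, (39 * 112) / (58 * 14), tolerance = 1e-6)
  expect_equal((39 * 112) / (58 * 14), 5.379, tolerance = 1e-3)
  expect_error(univariate_odds(factor(rep("a", 10), levels = c("a", "b")),
                               rep(0:1, 5)), "degenerate|level")
})

test_that("Wald CI covers the null in ~95% of independent-factor replicates", {
  set.seed(14)
  cover <- 0
  for (i in 1:200) {
    x <- rbinom(2000, 1, 0.4)
    y <- rbinom(2000, 1, 0.3)
    res <- univariate_odds(x, y)
    if (res$ci_low <= 1 && 1 <= res$ci_high) cover <- cover + 1
  }
  expect_gt(cover / 200, 0.90)
  expect_lt(cover / 200, 0.99)
})

test_that("nomogram recovers planted ER effect and informative rad-score", {
  rates <- default_clinical_rates()
  both <- 0; com_only_ok <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    y <- rep(c(1L, 0L), each = 80)
    clin <- do.call(rbind, lapply(y, sample_clinical_factors))
    com <- rnorm(160, mean = 1.2 * y)   # informative continuous score
    nomo <- tryCatch(build_nomogram(clin, com, y), error = function(e) NULL)
    if (!is.null(nomo) &&
        all(c("er", "com_rad_score") %in% nomo$predictors)) both <- both + 1
    # noise clinical factors: only the rad-score should survive
    clin_noise <- clin
    for (v in c("age_group", "er", "pr", "ki67"))
      clin_noise[[v]] <- sample(clin[[v]])
    nomo2 <- tryCatch(build_nomogram(clin_noise, com, y),
                      error = function(e) NULL)
    if (!is.null(nomo2) &&
        identical(nomo2$predictors, "com_rad_score")) com_only_ok <- com_only_ok + 1
  }
  expect_gte(both, 16)        # >= 80% of seeds keep both predictors
  expect_gte(com_only_ok, 11) # majority of seeds keep only the rad-score
})

test_that("nomogram probability equals the underlying multivariate fit", {
  set.seed(21)
  y <- rep(c(1L, 0L), each = 60)
  clin <- do.call(rbind, lapply(y, sample_clinical_factors))
  com <- rnorm(120, mean = y)
  nomo <- build_nomogram(clin, com, y)
  p <- predict_nomogram(nomo, clin, com)
  design <- nomo$design
  lp <- nomo$model$intercept +
    drop(design %*% nomo$model$coefficients)
  expect_equal(p, plogis(lp), tolerance = 1e-12)
})

test_that("points scale spans 0-100 and round-trips to probabilities", {
  set.seed(22)
  y <- rep(c(1L, 0L), each = 60)
  clin <- do.call(rbind, lapply(y, sample_clinical_factors))
  com <- rnorm(120, mean = 1.5 * y)
  nomo <- build_nomogram(clin, com, y)
  pts <- nomogram_points(nomo)
  spans <- vapply(pts$tables, function(t) max(t$points) - min(t$points), 0)
  expect_equal(max(spans), 100, tolerance = 1e-9)
  expect_true(all(vapply(pts$tables, function(t) min(t$points), 0) >= -1e-9))
  # probability curve strictly increases with total points
  expect_true(all(diff(pts$curve$probability) > 0))
  # reading points back reproduces the model probability
  total <- rowSums(vapply(names(pts$tables), function(nm) {
    t <- pts$tables[[nm]]
    approx(t$value, t$points, xout = nomo$design[, nm], rule = 2)$y
  }, numeric(nrow(nomo$design))))
  p_back <- plogis(pts$base + total / pts$points_per_unit)
  p_true <- predict_nomogram(nomo, clin, com)
  expect_lt(max(abs(p_back - p_true)), 0.005)
})
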