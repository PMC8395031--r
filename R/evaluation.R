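## Discrimination (AUC, DeLong), operating points, calibration, decision
## curves, and the cohort-description tests.

#' Mann-Whitney AUC
#'
#' \eqn{AUC = P(s^+ > s^-) + \frac{1}{2} P(s^+ = s^-)} over all
#' positive-negative pairs, computed via mid-ranks.
#'
#' @param scores Numeric vector.
#' @param labels Binary 0/1 vector; both classes nonempty.
#' @return Scalar AUC in [0, 1].
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_dwr("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## DeLong placement values: V10 (per positive) and V01 (per negative)
delong_placements <- function(scores, labels) {
  labels <- as.integer(labels)
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), 0)
  v01 <- vapply(y, function(yj) mean(psi(x, yj)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' DeLong confidence interval for a single AUC
#'
#' Normal-approximation CI with the DeLong structural-components variance,
#' truncated to [0, 1]. Perfect separation yields zero variance; the
#' result is then flagged degenerate.
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 labels (>= 2 per class).
#' @param level Confidence level (default 0.95).
#' @return List with \code{auc}, \code{ci_low}, \code{ci_high}, \code{se},
#'   \code{degenerate}.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  labels <- as.integer(labels)
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2)
    stop_dwr("need at least two cases per class")
  pl <- delong_placements(scores, labels)
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  zq <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(v)
  list(auc = pl$auc,
       ci_low = max(0, pl$auc - zq * se),
       ci_high = min(1, pl$auc + zq * se),
       se = se, degenerate = v == 0)
}

#' Paired DeLong test comparing two correlated AUCs
#'
#' Both score vectors must be computed on the same cases. The z statistic
#' uses the joint covariance of the placement values; the p-value is
#' two-sided.
#'
#' @param scores_a,scores_b Numeric score vectors on the same cases.
#' @param labels Binary 0/1 labels.
#' @return List with \code{auc_a}, \code{auc_b}, \code{z}, \code{p_value}.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop_dwr("score vectors and labels must cover the same cases")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  d <- pa$auc - pb$auc
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  if (v <= 0) return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p_value = 1))
  z <- d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Operating point at the maximum Youden index, with bootstrap CIs
#'
#' The cutoff maximises sensitivity + specificity - 1 over midpoints
#' between adjacent sorted unique scores (ties towards the lowest cutoff);
#' predictions are positive when the score strictly exceeds the cutoff.
#' Percentile confidence intervals come from a case-resampling bootstrap.
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 labels.
#' @param n_bootstrap Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap stream.
#' @param level Confidence level (default 0.95).
#' @return List with \code{cutoff}, \code{sensitivity}, \code{specificity},
#'   \code{accuracy}, each with \code{*_ci} bounds.
#' @export
operating_point <- function(scores, labels, n_bootstrap = 2000L, seed = 1L,
                            level = 0.95) {
  labels <- as.integer(labels)
  if (!sum(labels == 1) || !sum(labels == 0))
    stop_dwr("both classes must be present")
  point <- function(s, y) {
    u <- sort(unique(s))
    cuts <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u - 0.5
    cuts <- c(min(u) - 1, cuts)   # allow "call everything positive"
    stats_at <- vapply(cuts, function(ct) {
      pred <- s > ct
      sens <- sum(pred & y == 1) / sum(y == 1)
      spec <- sum(!pred & y == 0) / sum(y == 0)
      c(sens, spec)
    }, c(0, 0))
    j <- stats_at[1, ] + stats_at[2, ] - 1
    k <- which(j == max(j))[1]   # lowest qualifying cutoff
    pred <- s > cuts[k]
    c(cutoff = cuts[k], sensitivity = stats_at[1, k],
      specificity = stats_at[2, k],
      accuracy = mean(pred == (y == 1)))
  }
  est <- point(scores, labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boot <- t(vapply(seq_len(n_bootstrap), function(i) {
    repeat {
      idx <- sample.int(length(scores), replace = TRUE)
      if (length(unique(labels[idx])) == 2) break
    }
    point(scores[idx], labels[idx])
  }, est))
  alpha <- (1 - level) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  list(cutoff = est[["cutoff"]],
       sensitivity = est[["sensitivity"]],
       sensitivity_ci = unname(ci[, "sensitivity"]),
       specificity = est[["specificity"]],
       specificity_ci = unname(ci[, "specificity"]),
       accuracy = est[["accuracy"]],
       accuracy_ci = unname(ci[, "accuracy"]))
}

#' Calibration curve: observed vs predicted risk
#'
#' Groups cases into (at most) \code{n_groups} quantile bins of predicted
#' probability and reports the mean predicted and observed event rates per
#' bin, plus a lowess-smoothed curve.
#'
#' @param probabilities Predicted probabilities in [0, 1].
#' @param labels Binary 0/1 outcomes.
#' @param n_groups Number of risk groups (default 10; reduced with a
#'   warning when there are fewer cases).
#' @return List with \code{groups} (data.frame predicted/observed/n) and
#'   \code{smoothed} (data.frame predicted/observed).
#' @export
calibration_curve <- function(probabilities, labels, n_groups = 10L) {
  if (any(probabilities < 0 | probabilities > 1))
    stop_dwr("probabilities must lie in [0, 1]")
  labels <- as.integer(labels)
  n <- length(labels)
  if (n < n_groups) {
    warn_dwr("fewer cases (%d) than groups (%d): reducing", n, n_groups)
    n_groups <- max(1L, n)
  }
  qs <- unique(stats::quantile(probabilities,
                               probs = seq(0, 1, length.out = n_groups + 1)))
  grp <- if (length(qs) > 2)
    cut(probabilities, breaks = qs, include.lowest = TRUE, labels = FALSE)
  else rep(1L, n)
  groups <- data.frame(
    predicted = as.numeric(tapply(probabilities, grp, mean)),
    observed = as.numeric(tapply(labels, grp, mean)),
    n = as.integer(table(grp)))
  sm <- if (length(unique(probabilities)) > 2)
    stats::lowess(probabilities, labels, f = 2 / 3)
  else list(x = groups$predicted, y = groups$observed)
  list(groups = groups,
       smoothed = data.frame(predicted = sm$x, observed = sm$y))
}

#' Decision curve analysis
#'
#' Net benefit of treating above each threshold probability \eqn{p_t}:
#' \deqn{NB(p_t) = TP/n - (FP/n) \cdot p_t / (1 - p_t)}
#' against the treat-all strategy
#' (\eqn{\pi - (1 - \pi) p_t/(1 - p_t)}, \eqn{\pi} = prevalence) and
#' treat-none (identically 0).
#'
#' @param probabilities Predicted probabilities in [0, 1].
#' @param labels Binary 0/1 outcomes.
#' @param thresholds Grid of threshold probabilities strictly inside
#'   (0, 1); default 0.01--0.99 by 0.01.
#' @return data.frame with \code{threshold}, \code{net_benefit},
#'   \code{treat_all}, \code{treat_none}.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(probabilities < 0 | probabilities > 1))
    stop_dwr("probabilities must lie in [0, 1]")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop_dwr("thresholds must lie strictly in (0, 1)")
  labels <- as.integer(labels)
  n <- length(labels)
  prev <- mean(labels)
  nb <- vapply(thresholds, function(pt) {
    pred <- probabilities >= pt
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    tp / n - (fp / n) * pt / (1 - pt)
  }, 0)
  data.frame(threshold = thresholds,
             net_benefit = nb,
             treat_all = prev - (1 - prev) * thresholds / (1 - thresholds),
             treat_none = 0)
}

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#'
#' @param a,b,c,d Cell counts, row-wise.
#' @return List with \code{chi2} and \code{p_value} (df = 1).
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  if (any(tab < 0)) stop_dwr("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_dwr("all table margins must be positive")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Welch two-sample t test
#'
#' Unequal-variance two-sided t test, as used to compare rad-scores
#' between outcome groups.
#'
#' @param group_a,group_b Numeric vectors (n >= 2 each).
#' @return List with \code{t}, \code{df}, \code{p_value}.
#' @export
two_sample_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_dwr("each group needs at least two values")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = NA_real_, p_value = 1, degenerate = TRUE))
    return(list(t = Inf, df = NA_real_, p_value = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(group_a, group_b)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Full discrimination report for one model on one cohort
#'
#' @param scores Numeric scores (any monotone scale).
#' @param labels Binary 0/1 labels.
#' @param n_bootstrap Bootstrap resamples for the operating-point CIs.
#' @param seed Bootstrap seed.
#' @return List (class \code{evaluation_report}) with the DeLong AUC CI,
#'   the Youden operating point with CIs, and class counts.
#' @export
evaluate_scores <- function(scores, labels, n_bootstrap = 2000L, seed = 1L) {
  ci <- delong_ci(scores, labels)
  op <- operating_point(scores, labels, n_bootstrap = n_bootstrap,
                        seed = seed)
  structure(c(ci, op,
              list(n_pos = sum(labels == 1), n_neg = sum(labels == 0))),
            class = "evaluation_report")
}
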