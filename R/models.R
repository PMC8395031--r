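## Logistic modelling: rad-scores, univariate/multivariate odds ratios,
## and the points-scale nomogram.

## IRLS for logistic regression with an optional ridge penalty on the
## non-intercept coefficients (used as the separation fallback)
irls_logistic <- function(X, y, lambda = 0, max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)   # never penalise the intercept
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    H <- XtW %*% X + pen
    beta_new <- tryCatch(solve(H, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) return(NULL)
    beta_new <- drop(beta_new)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- t(X * w) %*% X + pen
  cov <- tryCatch(solve(H), error = function(e) matrix(NA, p, p))
  list(beta = beta, cov = cov, fitted = mu, iter = it,
       loglik = sum(y * log(pmax(mu, 1e-300)) +
                    (1 - y) * log(pmax(1 - mu, 1e-300))))
}

#' Fit a logistic regression model
#'
#' Maximum likelihood by iteratively reweighted least squares. When
#' (quasi-)complete separation is detected (fitted probabilities pinned at
#' 0/1 with diverging coefficients), the model is refitted with a small
#' ridge penalty \eqn{\lambda = 10^{-6} n} and flagged.
#'
#' @param design Numeric matrix or data.frame of predictors (no intercept
#'   column; one is added).
#' @param labels Binary 0/1 vector.
#' @return Object of class \code{logistic_model}: list with
#'   \code{feature_names}, \code{intercept}, \code{coefficients},
#'   \code{cov}, \code{converged}, \code{separation}, \code{aic},
#'   \code{fitted}.
#' @export
fit_logistic <- function(design, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop_dwr("labels contain a single class")
  X0 <- as.matrix(design)
  storage.mode(X0) <- "double"
  n <- length(y)
  if (n <= ncol(X0) + 1)
    stop_dwr("more parameters than cases")
  qrX <- qr(cbind(1, X0))
  if (qrX$rank < ncol(X0) + 1) {
    bad <- colnames(X0)[qrX$pivot[(qrX$rank + 1):(ncol(X0) + 1)] - 1L]
    stop_dwr("rank-deficient design; collinear columns: %s",
             paste(stats::na.omit(bad), collapse = ", "))
  }
  X <- cbind(`(Intercept)` = 1, X0)
  fit <- irls_logistic(X, y)
  separation <- is.null(fit) ||
    (max(abs(fit$beta)) > 30 && (min(fit$fitted) < 1e-8 || max(fit$fitted) > 1 - 1e-8))
  if (separation) {
    fit <- irls_logistic(X, y, lambda = 1e-6 * n)
    warn_dwr("separation detected: refitted with ridge penalty lambda = %.2g",
             1e-6 * n)
  }
  if (is.null(fit)) stop_dwr("logistic fit failed")
  k <- ncol(X)
  structure(list(feature_names = colnames(X0),
                 intercept = unname(fit$beta[1]),
                 coefficients = stats::setNames(fit$beta[-1], colnames(X0)),
                 cov = fit$cov,
                 converged = TRUE,
                 separation = separation,
                 aic = -2 * fit$loglik + 2 * k,
                 fitted = unname(fit$fitted)),
            class = "logistic_model")
}

#' Rad-score: the linear predictor of a fitted logistic model
#'
#' \eqn{score = \beta_0 + \sum_i \beta_i x_i}. The predicted probability is
#' \code{plogis(score)}.
#'
#' @param model A \code{logistic_model}.
#' @param features Numeric matrix/data.frame containing at least the
#'   model's feature columns, or a named vector for a single case.
#' @param include_intercept Include \eqn{\beta_0} (default TRUE).
#' @return Numeric vector of scores.
#' @export
rad_score <- function(model, features, include_intercept = TRUE) {
  stopifnot(inherits(model, "logistic_model"))
  nms <- model$feature_names
  if (is.null(dim(features))) features <- t(as.matrix(features))
  features <- as.matrix(features)
  if (!all(nms %in% colnames(features)))
    stop_dwr("missing features: %s",
             paste(setdiff(nms, colnames(features)), collapse = ", "))
  sc <- if (length(nms)) drop(features[, nms, drop = FALSE] %*% model$coefficients)
        else rep(0, nrow(features))
  if (include_intercept) sc <- sc + model$intercept
  unname(sc)
}

#' Univariate logistic association with odds ratio and Wald CI
#'
#' @param factor Numeric, logical or two-level factor predictor (reference
#'   category = first level).
#' @param labels Binary 0/1 outcome.
#' @param level Confidence level (default 0.95).
#' @return data.frame with \code{parameter}, \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{p_value} and a \code{separation} flag.
#' @export
univariate_odds <- function(factor, labels, level = 0.95) {
  x <- encode_predictor(factor)
  if (length(unique(x)) < 2) stop_dwr("degenerate factor: a single level")
  fit <- fit_logistic(matrix(x, ncol = 1, dimnames = list(NULL, "x")), labels)
  beta <- fit$coefficients[["x"]]
  se <- sqrt(fit$cov[2, 2])
  zq <- stats::qnorm(1 - (1 - level) / 2)
  z <- beta / se
  data.frame(parameter = attr(x, "label") %||% "x",
             or = exp(beta),
             ci_low = exp(beta - zq * se),
             ci_high = exp(beta + zq * se),
             p_value = 2 * stats::pnorm(-abs(z)),
             separation = fit$separation)
}

encode_predictor <- function(f) {
  if (is.factor(f)) {
    if (nlevels(f) != 2) stop_dwr("factors must have exactly two levels")
    structure(as.numeric(f) - 1, label = levels(f)[2])
  } else as.numeric(f)
}

## log-likelihood of a fitted logistic model (from its AIC)
loglik_of <- function(fit, n_params) (2 * n_params - fit$aic) / 2

## likelihood-ratio p-value for dropping one column from a design
lrt_p <- function(design, labels, drop_col) {
  y <- as.numeric(labels)
  full <- fit_logistic(design, y)
  keep <- setdiff(colnames(design), drop_col)
  ll_full <- loglik_of(full, ncol(design) + 1)
  ll_red <- if (length(keep)) {
    red <- fit_logistic(design[, keep, drop = FALSE], y)
    loglik_of(red, length(keep) + 1)
  } else {
    p <- mean(y)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  stats::pchisq(max(2 * (ll_full - ll_red), 0), df = 1, lower.tail = FALSE)
}

#' Build the clinical + rad-score nomogram
#'
#' Screens the candidate predictors (age group, ER, PR, Ki-67 status and
#' the combined rad-score) by univariate logistic regression at p < 0.05,
#' fits the multivariate logistic model on the survivors, retains the
#' multivariate p < 0.05 survivors as independent predictors, and refits
#' the final model on those. Retention decisions use likelihood-ratio
#' p-values, which stay informative when a predictor separates the
#' classes (where Wald statistics collapse); the association tables still
#' report Wald CIs and p-values for the odds ratios.
#'
#' @param clinical data.frame with factors \code{age_group}, \code{er},
#'   \code{pr}, \code{ki67}.
#' @param comrad Numeric combined rad-score per case.
#' @param labels Binary 0/1 outcome.
#' @param alpha Retention level (default 0.05).
#' @return Object of class \code{nomogram_model}: the final
#'   \code{logistic_model}, predictor names, the univariate and
#'   multivariate association tables, and the design used.
#' @export
build_nomogram <- function(clinical, comrad, labels, alpha = 0.05) {
  cand <- list(age_group = clinical$age_group, er = clinical$er,
               pr = clinical$pr, ki67 = clinical$ki67,
               com_rad_score = comrad)
  design <- sapply(cand, encode_predictor)
  colnames(design) <- names(cand)
  uni <- do.call(rbind, lapply(names(cand), function(nm) {
    res <- univariate_odds(cand[[nm]], labels)
    res$parameter <- nm
    res$p_lrt <- lrt_p(design[, nm, drop = FALSE], labels, nm)
    res
  }))
  survivors <- uni$parameter[uni$p_lrt < alpha]
  if (!length(survivors))
    stop_dwr("no candidate predictor passed the univariate screen at p < %.2f",
             alpha)
  multi_fit <- fit_logistic(design[, survivors, drop = FALSE], labels)
  zq <- stats::qnorm(0.975)
  se <- sqrt(diag(multi_fit$cov))[-1]
  beta <- multi_fit$coefficients
  multi <- data.frame(parameter = survivors, or = exp(beta),
                      ci_low = exp(beta - zq * se),
                      ci_high = exp(beta + zq * se),
                      p_value = 2 * stats::pnorm(-abs(beta / se)),
                      p_lrt = vapply(survivors, function(nm)
                        lrt_p(design[, survivors, drop = FALSE], labels, nm),
                        0),
                      row.names = NULL)
  independent <- multi$parameter[multi$p_lrt < alpha]
  if (!length(independent))
    stop_dwr("no independent predictor at multivariate p < %.2f", alpha)
  final <- fit_logistic(design[, independent, drop = FALSE], labels)
  structure(list(model = final, predictors = independent,
                 univariate = uni, multivariate = multi,
                 design = design[, independent, drop = FALSE]),
            class = "nomogram_model")
}

#' Predicted probability from a nomogram
#'
#' @param nomo A \code{nomogram_model}.
#' @param clinical data.frame of clinical factors for the cases to score.
#' @param comrad Combined rad-score per case.
#' @return Numeric vector of probabilities.
#' @export
predict_nomogram <- function(nomo, clinical, comrad) {
  stopifnot(inherits(nomo, "nomogram_model"))
  cand <- list(age_group = clinical$age_group, er = clinical$er,
               pr = clinical$pr, ki67 = clinical$ki67,
               com_rad_score = comrad)
  design <- sapply(cand, encode_predictor)
  colnames(design) <- names(cand)
  stats::plogis(rad_score(nomo$model, design))
}

#' Points scale of a nomogram
#'
#' Each predictor contributes \eqn{\beta (x - x_{min})} on the linear
#' predictor scale; contributions are rescaled so the predictor with the
#' largest contribution range spans exactly 0--100 points. The total-points
#' to probability curve inverts the scaling back to the linear predictor.
#'
#' @param nomo A \code{nomogram_model}.
#' @param n_curve Number of points on the probability curve (default 100).
#' @return List with \code{points_per_unit}, per-predictor \code{tables}
#'   (value, points), \code{base} (linear predictor at all-minimum
#'   predictors) and a \code{curve} data.frame (total_points,
#'   probability).
#' @export
nomogram_points <- function(nomo, n_curve = 100L) {
  stopifnot(inherits(nomo, "nomogram_model"))
  beta <- nomo$model$coefficients
  X <- nomo$design
  rng <- apply(X, 2, range)
  contrib_range <- abs(beta) * (rng[2, ] - rng[1, ])
  if (all(contrib_range == 0)) stop_dwr("all predictors have zero range")
  unit <- 100 / max(contrib_range)   # points per unit of |linear predictor|
  ## reference value (0 points) is the end of the range that minimises the
  ## predictor's contribution, so points are always nonnegative and
  ## linear predictor = base + total_points / unit
  x_ref <- ifelse(beta >= 0, rng[1, ], rng[2, ])
  tables <- lapply(colnames(X), function(nm) {
    vals <- if (length(unique(X[, nm])) <= 2) sort(unique(X[, nm]))
            else seq(rng[1, nm], rng[2, nm], length.out = 11)
    data.frame(value = vals,
               points = unit * beta[nm] * (vals - x_ref[nm]))
  })
  names(tables) <- colnames(X)
  base <- nomo$model$intercept + sum(beta * x_ref)
  total_rng <- c(0, sum(vapply(tables, function(t) max(t$points), 0)))
  tp <- seq(total_rng[1], total_rng[2], length.out = n_curve)
  curve <- data.frame(total_points = tp,
                      probability = stats::plogis(base + tp / unit))
  list(points_per_unit = unit, tables = tables, base = base, curve = curve)
}
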