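## Three-step feature selection: Wilcoxon screen, MRMR, backward stepwise AIC.

#' Wilcoxon rank-sum screen
#'
#' Two-sided rank-sum test per feature between the two label groups.
#' Exact p-values are used when the total sample size is at most 12 and no
#' ties are present; otherwise the continuity-corrected normal
#' approximation with mid-rank ties, the standard choice at clinical
#' cohort sizes. Features with p strictly below \code{alpha} survive.
#'
#' @param table Numeric matrix (cases x features).
#' @param labels 0/1 vector, both classes nonempty.
#' @param alpha Screening level (default 0.1).
#' @return List with \code{p_values} (named vector) and \code{screened}
#'   (surviving feature names).
#' @export
wilcoxon_screen <- function(table, labels, alpha = 0.1) {
  table <- as.matrix(table)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop_dwr("both classes must be present")
  exact <- length(labels) <= 12
  p <- vapply(seq_len(ncol(table)), function(j) {
    x <- table[labels == 1, j]
    y <- table[labels == 0, j]
    use_exact <- exact && !anyDuplicated(c(x, y))
    suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                        correct = TRUE)$p.value)
  }, 0)
  names(p) <- colnames(table)
  list(p_values = p, screened = colnames(table)[p < alpha])
}

## equal-frequency discretisation into (at most) n_bins levels
discretize_ef <- function(x, n_bins = 8L) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               type = 7))
  if (length(qs) < 2) return(rep(1L, length(x)))
  cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

## mutual information (nats) between two discrete vectors
mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

#' Greedy MRMR feature selection (MID criterion)
#'
#' Forward selection maximising \eqn{I(f; y) - \frac{1}{|S|}\sum_{s \in S}
#' I(f; s)}: mutual information between the equal-frequency-discretised
#' feature and the binary label, penalised by the mean mutual information
#' with the already-selected set (the difference, MID, criterion). The
#' quotient (MIQ) variant is available via \code{criterion}.
#'
#' @param table Numeric matrix (cases x features).
#' @param labels Binary 0/1 vector.
#' @param k Number of features to select (default 20); if fewer candidates
#'   exist, all are returned with a warning.
#' @param n_bins Discretisation bins (default 8).
#' @param criterion \code{"MID"} (difference, default) or \code{"MIQ"}
#'   (quotient).
#' @return Character vector of selected names in greedy order.
#' @export
mrmr_select <- function(table, labels, k = 20L, n_bins = 8L,
                        criterion = c("MID", "MIQ")) {
  criterion <- match.arg(criterion)
  table <- as.matrix(table)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop_dwr("labels must be binary 0/1")
  if (!ncol(table)) stop_dwr("no candidate features")
  if (ncol(table) < k) {
    warn_dwr("only %d candidates for k = %d: returning all", ncol(table), k)
    k <- ncol(table)
  }
  disc <- apply(table, 2, discretize_ef, n_bins = n_bins)
  relevance <- apply(disc, 2, mutual_information, b = labels)
  selected <- character(0)
  pool <- colnames(table)
  red_sum <- stats::setNames(numeric(length(pool)), pool)
  for (step in seq_len(k)) {
    if (!length(selected)) {
      score <- relevance[pool]
    } else {
      mean_red <- red_sum[pool] / length(selected)
      score <- if (criterion == "MID") relevance[pool] - mean_red
               else relevance[pool] / pmax(mean_red, .Machine$double.eps)
    }
    best <- pool[which.max(score)]   # first index wins ties: stable order
    selected <- c(selected, best)
    pool <- setdiff(pool, best)
    if (!length(pool)) break
    add <- vapply(pool, function(f)
      mutual_information(disc[, f], disc[, best]), 0)
    red_sum[pool] <- red_sum[pool] + add
  }
  selected
}

#' Backward stepwise logistic elimination under AIC
#'
#' Starts from the full logistic model over the candidate features and
#' repeatedly removes the single feature whose removal most decreases the
#' AIC, stopping when no removal decreases it. This AIC comparison is
#' equivalent to a likelihood-ratio stopping rule with penalty 2 per
#' parameter. Ties are broken by lexicographic feature name.
#'
#' @param table Numeric matrix (cases x features), candidates only.
#' @param labels Binary 0/1 vector.
#' @return List with \code{final} (retained names, possibly empty),
#'   \code{aic_path} (AIC after the initial fit and each accepted
#'   elimination) and \code{dropped} (names in elimination order).
#' @export
backward_stepwise <- function(table, labels) {
  table <- as.matrix(table)
  labels <- as.integer(labels)
  current <- colnames(table)
  fit_aic <- function(feats) {
    if (!length(feats)) {
      fit <- suppressWarnings(stats::glm(labels ~ 1, family = stats::binomial()))
    } else {
      df <- as.data.frame(table[, feats, drop = FALSE])
      fit <- suppressWarnings(stats::glm(labels ~ ., data = df,
                                         family = stats::binomial()))
    }
    fit$aic
  }
  aic <- fit_aic(current)
  path <- aic
  dropped <- character(0)
  while (length(current)) {
    cand <- sort(current)   # lexicographic tie-break
    aics <- vapply(cand, function(f) fit_aic(setdiff(current, f)), 0)
    j <- which.min(aics)
    if (aics[j] < aic - 1e-10) {
      aic <- aics[j]
      dropped <- c(dropped, cand[j])
      current <- setdiff(current, cand[j])
      path <- c(path, aic)
    } else break
  }
  list(final = current, aic_path = path, dropped = dropped)
}

#' Three-step feature selection for one region pool
#'
#' Wilcoxon screen at \code{alpha}, MRMR down to \code{k}, then backward
#' stepwise AIC, with the nesting final \eqn{\subseteq} MRMR
#' \eqn{\subseteq} screened guaranteed by construction.
#'
#' @param table Numeric matrix (training cases x candidate features).
#' @param labels Binary 0/1 vector.
#' @param alpha Screen level (default 0.1).
#' @param k MRMR size (default 20).
#' @param n_bins MRMR discretisation bins.
#' @return List (class \code{selection_trace}) with \code{p_values},
#'   \code{screened}, \code{mrmr}, \code{final}, \code{aic_path}.
#' @export
select_features <- function(table, labels, alpha = 0.1, k = 20L,
                            n_bins = 8L) {
  scr <- wilcoxon_screen(table, labels, alpha)
  ## drop exact duplicates (e.g. the orientation-degenerate f=0 Gabor
  ## kernels yield identical columns), keeping the first in registry order
  if (length(scr$screened) > 1) {
    sub <- as.matrix(table)[, scr$screened, drop = FALSE]
    scr$screened <- scr$screened[!duplicated(t(sub))]
  }
  if (!length(scr$screened))
    return(structure(list(p_values = scr$p_values, screened = character(0),
                          mrmr = character(0), final = character(0),
                          aic_path = numeric(0)), class = "selection_trace"))
  mr <- mrmr_select(as.matrix(table)[, scr$screened, drop = FALSE],
                    labels, k = k, n_bins = n_bins)
  bs <- backward_stepwise(as.matrix(table)[, mr, drop = FALSE], labels)
  structure(list(p_values = scr$p_values, screened = scr$screened,
                 mrmr = mr, final = bs$final, aic_path = bs$aic_path),
            class = "selection_trace")
}
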