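## Two-reader feature stability: intraclass correlation filtering.

#' Two-way random-effects, absolute-agreement, single-measure ICC
#'
#' ICC(2,1) from the standard two-way ANOVA decomposition over an
#' n-cases x k-raters layout:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + k(MS_C - MS_E)/n}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the rows (cases), columns
#' (raters) and residual mean squares. The consistency form ICC(3,1) is
#' available via \code{type = "consistency"}.
#'
#' @param x Numeric matrix, cases in rows, raters in columns (k >= 2).
#' @param type \code{"agreement"} (default, ICC(2,1)) or
#'   \code{"consistency"} (ICC(3,1)).
#' @return Scalar ICC estimate; \code{NA} with a \code{"degenerate"}
#'   attribute when fewer than 3 cases or zero total variance.
#' @export
icc_two_way_random <- function(x, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (k < 2) stop_dwr("ICC needs at least two raters")
  if (any(!is.finite(x))) stop_dwr("ICC input must be complete")
  if (n < 3 || stats::var(as.vector(x)) == 0)
    return(structure(NA_real_, degenerate = TRUE))
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ms_r <- k * sum((row_m - grand)^2) / (n - 1)
  ms_c <- n * sum((col_m - grand)^2) / (k - 1)
  ss_tot <- sum((x - grand)^2)
  ss_e <- ss_tot - k * sum((row_m - grand)^2) - n * sum((col_m - grand)^2)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  if (type == "consistency") {
    denom <- ms_r + (k - 1) * ms_e
    if (denom == 0) return(structure(NA_real_, degenerate = TRUE))
    return((ms_r - ms_e) / denom)
  }
  denom <- ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n
  if (denom == 0) return(structure(NA_real_, degenerate = TRUE))
  (ms_r - ms_e) / denom
}

#' Filter features by two-reader ICC
#'
#' Computes a per-feature ICC between two readers' extractions of the same
#' cases and retains the features whose ICC strictly exceeds the threshold.
#' Degenerate features (zero variance) are never retained.
#'
#' @param table_a,table_b Numeric matrices (cases x features) with
#'   identical dimnames: one per reader.
#' @param threshold Retention threshold (default 0.8, strict inequality).
#' @param type ICC form, see \code{\link{icc_two_way_random}}.
#' @return List with \code{results} (data.frame feature/icc/retained) and
#'   \code{retained} (character vector of feature names).
#' @export
icc_filter <- function(table_a, table_b, threshold = 0.8,
                       type = "agreement") {
  table_a <- as.matrix(table_a); table_b <- as.matrix(table_b)
  if (!identical(dim(table_a), dim(table_b)) ||
      !identical(colnames(table_a), colnames(table_b)))
    stop_dwr("reader tables must have identical cases and features")
  if (!is.null(rownames(table_a)) &&
      !identical(rownames(table_a), rownames(table_b)))
    stop_dwr("reader tables must cover the same cases in the same order")
  icc <- vapply(seq_len(ncol(table_a)), function(j)
    as.numeric(icc_two_way_random(cbind(table_a[, j], table_b[, j]),
                                  type = type)), 0)
  retained <- !is.na(icc) & icc > threshold
  res <- data.frame(feature = colnames(table_a), icc = icc,
                    retained = retained, row.names = NULL)
  list(results = res, retained = res$feature[retained])
}
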