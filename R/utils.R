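#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dwr <- function(...) stop(sprintf(...), call. = FALSE)

warn_dwr <- function(...) warning(sprintf(...), call. = FALSE)

assert_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop_dwr("%s must share the same shape (got %s vs %s)", what,
             paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

assert_mask <- function(mask, allow_empty = FALSE) {
  if (!is.matrix(mask)) stop_dwr("mask must be a matrix")
  m <- mask != 0
  if (!allow_empty && !any(m)) stop_dwr("mask is empty")
  m
}

#' Derive a child seed for a pipeline stage
#'
#' One global seed fans out deterministically to per-stage seeds so that any
#' stage can be re-run in isolation and reproduce the same stream.
#'
#' @param seed Integer master seed.
#' @param stage Character stage tag (e.g. \code{"cohort"}, \code{"icc"}).
#' @return A positive integer below \code{2^31}.
#' @export
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 131) %% 2147483629L + 1)
}

#' Percentage of a count over a total
#'
#' Convenience used throughout cohort summaries: \code{100 * num / den},
#' rounded to two decimals as printed in clinical tables.
#'
#' @param num Numerator count.
#' @param den Denominator count (> 0).
#' @param digits Decimal places to keep (default 2).
#' @return Numeric percentage.
#' @export
rate_percent <- function(num, den, digits = 2) {
  if (den <= 0) stop_dwr("denominator must be positive")
  round(100 * num / den, digits)
}

## bounding box of a logical mask: rows/cols ranges (list r1,r2,c1,c2)
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  list(r1 = min(idx[, 1]), r2 = max(idx[, 1]),
       c1 = min(idx[, 2]), c2 = max(idx[, 2]))
}

## clamp a bbox expanded by `pad` to matrix bounds
expand_bbox <- function(bb, pad, dims) {
  list(r1 = max(1L, bb$r1 - pad), r2 = min(dims[1], bb$r2 + pad),
       c1 = max(1L, bb$c1 - pad), c2 = min(dims[2], bb$c2 + pad))
}

crop_bbox <- function(x, bb) x[bb$r1:bb$r2, bb$c1:bb$c2, drop = FALSE]
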